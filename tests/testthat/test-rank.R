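test_that("candidate enumeration covers singletons and unordered pairs", {
  vocab14 <- adrnet:::default_drug_names(14L)
  cands <- enumerate_candidates(vocab14)
  expect_length(cands, 105L)
  expect_equal(sum(lengths(cands) == 1L), 14L)
  expect_equal(sum(lengths(cands) == 2L), 91L)
  # brute-force oracle for several vocabulary sizes
  for (n in c(1, 2, 4, 9, 14)) {
    v <- vocab14[seq_len(n)]
    got <- enumerate_candidates(v)
    expect_length(got, n + choose(n, 2))
    keys <- sort(vapply(got, function(d) paste(sort(d), collapse = ";"),
                        character(1)))
    grid <- expand.grid(a = v, b = v, stringsAsFactors = FALSE)
    brute <- unique(vapply(seq_len(nrow(grid)), function(i)
      paste(sort(unique(c(grid$a[i], grid$b[i]))), collapse = ";"),
      character(1)))
    expect_identical(keys, sort(brute))
  }
  expect_length(enumerate_candidates("X"), 1L)
  expect_length(enumerate_candidates(letters[1:4]), 10L)
  expect_error(enumerate_candidates(character(0)), "empty")
  expect_error(enumerate_candidates(letters[1:3], 3), "1 or 2")
})

test_that("prescription ranking sorts ascending with lexicographic ties", {
  feats <- tiny_features()
  pm <- planted_model(schema = tiny_schema(), vocabulary = tiny_vocab(),
                      d = 3, d_prime = 2, seed = 6)
  # nil drug head: every candidate ties; order must be lexicographic
  nil <- pm; nil$params$W[4:5] <- 0
  rk <- rank_prescriptions(nil, feats, "A", 20, 4)
  expect_equal(nrow(rk), 6L)    # 3 singles + 3 pairs
  expect_identical(rk$prescription, sort(rk$prescription))
  expect_equal(rk$rank, 1:6)
  expect_equal(length(unique(round(rk$predicted_hamd, 10))), 1L)
  # plant a dominant drug: make MIRTAZAPINE strongly score-lowering
  dom <- pm
  dom$params$E_A["MIRTAZAPINE", ] <- c(50, 50)
  wA <- dom$params$W[4:5]
  if (sum(wA) > 0) dom$params$E_A["MIRTAZAPINE", ] <- c(-50, -50)
  rk2 <- rank_prescriptions(dom, feats, "A", 20, 4,
                            candidates = as.list(tiny_vocab()))
  expect_equal(rk2$prescription[1], "MIRTAZAPINE")
  # predictions are invariant to candidate input order
  cands <- enumerate_candidates(tiny_vocab())
  a <- rank_prescriptions(pm, feats, "A", 20, 4, candidates = cands)
  b <- rank_prescriptions(pm, feats, "A", 20, 4, candidates = rev(cands))
  expect_identical(a, b)
  expect_setequal(a$prescription,
                  vapply(cands, function(d) paste(sort(d), collapse = ";"),
                         character(1)))
  one <- rank_prescriptions(pm, feats, "A", 20, 4,
                            candidates = list("SERTRALINE"))
  expect_equal(one$rank, 1L)
})

test_that("policy simulation reproduces the rollout and the best policy wins stepwise", {
  sim <- generate_cohort(sim_config(n_patients = 6,
                                    feature_sizes = tiny_schema(),
                                    missing_rate = 0, seed = 35))
  ex <- build_pairs(sim$visits)
  fit <- adrnet(ex, sim$features, sim$vocabulary, d = 3, d_prime = 2,
                epochs = 40, seed = 2)
  v1 <- sim$visits[sim$visits$patient_id == "P001", ]
  actual <- simulate_policy(fit, v1, sim$features, policy = "actual")
  ro <- rollout_remission(fit, v1, sim$features)
  expect_equal(actual$hamd_pred[nrow(actual)], ro$hamd_final_pred)
  expect_equal(actual$hamd_pred[1], v1$hamd[1])
  expect_identical(actual$prescription[-nrow(actual)],
                   v1$drugs[-nrow(v1)])
  # the best policy picks the argmin candidate, so its first transition
  # cannot predict a higher score than the recorded prescription's
  best <- simulate_policy(fit, v1, sim$features, policy = "best")
  expect_lte(best$hamd_pred[2], actual$hamd_pred[2] + 1e-10)
  expect_error(simulate_policy(fit, v1[1, ], sim$features), "two visits")
})

test_that("patient embeddings are the patient-layer activations", {
  sim <- generate_cohort(sim_config(n_patients = 10,
                                    feature_sizes = tiny_schema(),
                                    missing_rate = 0, seed = 36))
  ex <- build_pairs(sim$visits)
  fit <- adrnet(ex, sim$features, sim$vocabulary, d = 3, d_prime = 2,
                epochs = 30, seed = 2)
  emb <- embed_patients(fit, sim$visits, sim$features)
  expect_equal(dim(emb), c(10L, 3L))
  expect_identical(rownames(emb), unique(sim$visits$patient_id))
  # duplicating a patient's features and final state duplicates the vector
  feats2 <- lapply(sim$features, function(m) {
    m2 <- rbind(m, m["P003", , drop = FALSE])
    rownames(m2)[nrow(m2)] <- "P999"
    m2
  })
  v2 <- sim$visits[sim$visits$patient_id == "P003", ]
  v2$patient_id <- "P999"
  emb2 <- embed_patients(fit, rbind(sim$visits, v2), feats2)
  expect_equal(emb2["P999", ], emb2["P003", ])
})

test_that("nearest-neighbour retrieval ranks by cosine similarity", {
  idx <- rbind(a = c(1, 0), b = c(1, 1), c = c(0, 1))
  nn <- nearest_patients(c(1, 0), idx, k = 3)
  expect_identical(nn$patient_id, c("a", "b", "c"))
  expect_equal(nn$similarity, c(1, cos(pi / 4), 0), tolerance = 1e-12)
  # querying by id puts the member itself first with similarity 1
  self <- nearest_patients("b", idx, k = 2)
  expect_equal(self$patient_id[1], "b")
  expect_equal(self$similarity[1], 1)
  expect_error(nearest_patients(c(0, 0), idx, k = 1), "zero-norm")
  expect_error(nearest_patients(c(1, 0), idx, k = 9), "exceeds")
  # symmetry and boundedness of the similarity
  set.seed(42)
  for (i in 1:20) {
    u <- rnorm(4); v <- rnorm(4)
    s1 <- adrnet:::cosine_sim(u, matrix(v, 1))
    s2 <- adrnet:::cosine_sim(v, matrix(u, 1))
    expect_equal(s1, s2)
    expect_true(abs(s1) <= 1 + 1e-12)
  }
})

test_that("two planted response profiles separate in embedding space", {
  # two feature clusters with distinct response profiles
  set.seed(50)
  sch <- tiny_schema()
  n <- 60
  ids <- sprintf("C%03d", seq_len(n))
  grp <- rep(c(0, 3), each = n / 2)
  feats <- lapply(sch, function(p) {
    m <- matrix(rnorm(n * p, mean = grp), n, p); rownames(m) <- ids; m
  })
  ex <- data.frame(patient_id = ids, hamd_now = runif(n, 15, 25),
                   interval = 4,
                   drugs = sample(tiny_vocab(), n, TRUE),
                   stringsAsFactors = FALSE)
  X <- adrnet:::build_design(feats, ex)
  ex$hamd_next <- ifelse(grp > 0, ex$hamd_now - 8, ex$hamd_now) +
    rnorm(n, 0, 0.5)
  fit <- adrnet(ex, feats, tiny_vocab(), d = 3, d_prime = 2, epochs = 150,
                seed = 5)
  visits <- data.frame(patient_id = rep(ids, each = 2),
                       visit_index = rep(1:2, n),
                       weeks_since_prev = rep(c(NA, 4), n),
                       hamd = as.vector(rbind(ex$hamd_now, ex$hamd_next)),
                       drugs = rep(ex$drugs, each = 2),
                       stringsAsFactors = FALSE)
  visits$hamd <- pmax(visits$hamd, 1)
  emb <- embed_patients(fit, visits, feats)
  cs <- function(i, j) sum(emb[i, ] * emb[j, ]) /
    sqrt(sum(emb[i, ]^2) * sum(emb[j, ]^2))
  pairs_within <- t(combn(1:15, 2))
  within_sim <- mean(c(apply(pairs_within, 1, function(p) cs(p[1], p[2])),
                       apply(pairs_within + n / 2, 1,
                             function(p) cs(p[1], p[2]))), na.rm = TRUE)
  between_sim <- mean(sapply(1:15, function(i) cs(i, i + n / 2)),
                      na.rm = TRUE)
  expect_gt(within_sim, between_sim)
  cl <- cluster_patients(emb, k = 2, seed = 1)
  expect_length(cl, n)
  expect_setequal(unique(cl), 1:2)
})
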
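test_that("input assembly concatenates blocks with score and interval", {
  f <- list(demographic = c(1, 2), biomarkers = c(3, 4),
            variants = c(5, 6), methylation = c(7, 8))
  x <- assemble_input(f, hamd_now = 20, interval = 4)
  expect_identical(x, c(1, 2, 3, 4, 5, 6, 7, 8, 20, 4))
  z <- lapply(f, function(v) v * 0)
  expect_identical(assemble_input(z, 0, 0), rep(0, 10))
  bad <- f; bad$variants <- c(5, 6, 7)
  expect_error(assemble_input(bad, 20, 4,
                              schema = vapply(f, length, integer(1))),
               "variants")
})

test_that("patient representation is the activated affine map", {
  p <- list(W_P = matrix(0, 2, 3), b_P = rep(0, 3))
  expect_equal(as.vector(patient_repr(c(1, 2), p)), rep(0, 3))
  p$b_P <- rep(-1, 3)
  expect_equal(as.vector(patient_repr(c(1, 2), p)), rep(0, 3))  # clipped
  # 2-input single-unit toy: (1, 2) . (1, 1) + 0.5 = 3.5
  p2 <- list(W_P = matrix(c(1, 1), 2, 1), b_P = 0.5)
  expect_equal(as.vector(patient_repr(c(1, 2), p2)), 3.5)
  expect_equal(as.vector(patient_repr(c(1, 2), p2, "tanh")), tanh(3.5))
  expect_error(patient_repr(c(1, NA), p2), "non-finite")
})

test_that("prescription representation sums embedding rows", {
  E <- matrix(1:6, 3, 2, dimnames = list(c("X", "Y", "Z"), NULL))
  expect_equal(prescription_repr("Y", E), c(2, 5))
  expect_equal(prescription_repr(c("X", "Z"), E), c(1 + 3, 4 + 6))
  expect_equal(prescription_repr("X;Z", E), c(4, 10))
  expect_equal(prescription_repr("X", E * 0), c(0, 0))
  expect_error(prescription_repr("Q", E), "unknown drug")
  expect_error(prescription_repr(character(0), E), "empty prescription")
  # additivity over disjoint drug sets
  expect_equal(prescription_repr(c("X", "Y", "Z"), E),
               prescription_repr("X", E) + prescription_repr(c("Y", "Z"), E))
})

test_that("prediction composes the two branches with a linear head", {
  feats <- tiny_features()
  pm <- planted_model(schema = tiny_schema(), vocabulary = tiny_vocab(),
                      d = 3, d_prime = 2, seed = 5)
  ex <- data.frame(patient_id = c("A", "B"), hamd_now = c(20, 15),
                   interval = c(4, 1),
                   drugs = c("FLUOXETINE", "SERTRALINE;MIRTAZAPINE"),
                   stringsAsFactors = FALSE)
  # constant model: zero head weights, bias 7
  cm <- pm; cm$params$W[] <- 0; cm$params$b <- 7
  expect_equal(predict(cm, ex, feats), c(7, 7))
  # hand-composed 1+1 toy: V_P = 3.5, V_A = 2, W = (1, 1), b = 0 -> 5.5
  X <- adrnet:::build_design(feats, ex[1, ])
  toy <- pm
  toy$config$d <- 1L; toy$config$d_prime <- 1L
  toy$params <- list(W_P = matrix(0, ncol(X), 1), b_P = 3.5,
                     E_A = matrix(2, 3, 1,
                                  dimnames = list(tiny_vocab(), NULL)),
                     W = c(1, 1), b = 0)
  expect_equal(predict(toy, ex[1, ], feats), 5.5)
  # full forward pass equals the explicit composition
  vp <- patient_repr(X, pm$params)
  va <- prescription_repr("FLUOXETINE", pm$params$E_A)
  expect_equal(predict(pm, ex[1, ], feats),
               sum(c(vp, va) * pm$params$W) + pm$params$b)
  expect_error(predict(pm, transform(ex, drugs = ""), feats),
               "empty prescription")
})

test_that("mean squared error follows the definition", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 3)), 5)
  expect_equal(mse_loss(2, 5), 9)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:3, 1:2), "equal length")
})

test_that("analytic gradients match central differences on random models", {
  set.seed(20)
  checked <- 0L
  while (checked < 6L) {
    d <- sample(2:4, 1); dp <- 2L; p <- sample(5:8, 1); n <- 6L
    params <- adrnet:::init_params(p, d, dp, 3L, 0.5)
    X <- matrix(rnorm(n * p), n, p)
    M <- matrix(rbinom(n * 3, 1, 0.5), n, 3); M[rowSums(M) == 0, 1] <- 1
    y <- rnorm(n, 10, 3)
    # keep preactivations away from the ReLU kink so the finite-difference
    # oracle is valid
    if (min(abs(sweep(X %*% params$W_P, 2, params$b_P, `+`))) < 1e-3) next
    a <- adrnet:::loss_and_grads(params, X, M, y, "relu", l2 = 1e-3)$grads
    g <- adrnet:::numeric_grads(params, X, M, y, "relu", l2 = 1e-3)
    for (nm in names(a))
      expect_lt(max(abs(a[[nm]] - g[[nm]]) /
                      pmax(abs(a[[nm]]) + abs(g[[nm]]), 1e-4)), 1e-5)
    checked <- checked + 1L
  }
  # smooth nonlinearities need no kink guard
  params <- adrnet:::init_params(6, 3, 2, 3, 0.5)
  X <- matrix(rnorm(5 * 6), 5, 6)
  M <- diag(3)[c(1, 2, 3, 1, 2), ]
  y <- rnorm(5)
  for (nl in c("tanh", "sigmoid", "identity")) {
    a <- adrnet:::loss_and_grads(params, X, M, y, nl, l2 = 0)$grads
    g <- adrnet:::numeric_grads(params, X, M, y, nl, l2 = 0)
    for (nm in names(a))
      expect_lt(max(abs(a[[nm]] - g[[nm]]) /
                      pmax(abs(a[[nm]]) + abs(g[[nm]]), 1e-4)), 1e-5)
  }
})

test_that("training is seeded, converges on realizable data, and respects epochs", {
  dat <- tiny_planted(n = 300, noise_sd = 0)
  fit <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3, d_prime = 2,
                dropout = 0, l2 = 0, learning_rate = 0.01, epochs = 500,
                seed = 8)
  # realizable noise-free target: the training fit explains > 99% of the
  # target variance
  expect_lt(fit$loss[length(fit$loss)],
            0.01 * var(dat$examples$hamd_next))
  # refit with the same seed is bit-identical
  fit2 <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3,
                 d_prime = 2, dropout = 0, l2 = 0, learning_rate = 0.01,
                 epochs = 500, seed = 8)
  expect_identical(fit$params, fit2$params)
  # zero epochs returns the Gaussian initialisation untouched
  init <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3,
                 d_prime = 2, epochs = 0, seed = 8)
  ref <- adrnet:::with_seed(8L, adrnet:::init_params(
    sum(tiny_schema()) + 2L, 3L, 2L, 3L, 0.1))
  rownames(ref$E_A) <- tiny_vocab()
  expect_identical(init$params, ref)
})

test_that("the L2 penalty shrinks trained weights", {
  dat <- tiny_planted(n = 120, noise_sd = 0.5)
  free <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3,
                 d_prime = 2, dropout = 0, l2 = 0, epochs = 300, seed = 2)
  pen <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3,
                d_prime = 2, dropout = 0, l2 = 0.5, epochs = 300, seed = 2)
  norm2 <- function(p) sum(p$W_P^2) + sum(p$E_A^2) + sum(p$W^2)
  expect_lt(norm2(pen$params), norm2(free$params))
})

test_that("with identity activation the class contains the linear model", {
  # noise-free data generated by a linear rule; a width >= input identity
  # network must match the OLS oracle's training error
  set.seed(30)
  sch <- tiny_schema()
  n <- 80
  ids <- sprintf("L%03d", seq_len(n))
  feats <- lapply(sch, function(p) {
    m <- matrix(rnorm(n * p), n, p); rownames(m) <- ids; m
  })
  ex <- data.frame(patient_id = ids,
                   hamd_now = runif(n, 10, 30),
                   interval = sample(c(1, 3, 4), n, TRUE),
                   drugs = sample(tiny_vocab(), n, TRUE),
                   stringsAsFactors = FALSE)
  X <- adrnet:::build_design(feats, ex)
  M <- adrnet:::drug_incidence(ex$drugs, tiny_vocab())
  beta <- rnorm(ncol(X), 0, 0.3)
  ex$hamd_next <- as.vector(X %*% beta + M %*% c(-2, 0, 2)) + 15
  fit <- adrnet(ex, feats, tiny_vocab(), d = ncol(X), d_prime = 2,
                nonlinearity = "identity", dropout = 0, l2 = 0,
                learning_rate = 0.01, epochs = 400, seed = 3)
  ols <- lm.fit(cbind(1, X, M), ex$hamd_next)
  ols_mse <- mean(ols$residuals^2)
  expect_lt(mean(residuals(fit)^2), ols_mse + 1e-3)
})

test_that("hyperparameter search returns the grid row with lowest CV error", {
  dat <- tiny_planted(n = 80, noise_sd = 0.3)
  one <- tune_adrnet(dat$examples, dat$features, tiny_vocab(),
                     grid = data.frame(d = 3, d_prime = 2), k = 2,
                     epochs = 30, seed = 1)
  expect_equal(one$best$d, 3)
  expect_error(tune_adrnet(dat$examples, dat$features, tiny_vocab(),
                           grid = data.frame(d = 2), k = 100),
               "folds")
  expect_error(tune_adrnet(dat$examples, dat$features, tiny_vocab(),
                           grid = data.frame(d = integer(0)), k = 2),
               "empty")
})

test_that("checkpoints round-trip bit-faithfully", {
  dat <- tiny_planted(n = 40, noise_sd = 0.2)
  fit <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3, d_prime = 2,
                epochs = 15, seed = 4)
  dir <- withr::local_tempdir()
  save_adrnet(fit, dir)
  back <- load_adrnet(dir)
  expect_identical(back$params, fit$params)
  expect_identical(back$vocabulary, fit$vocabulary)
  expect_identical(unname(back$schema), unname(fit$schema))
  expect_identical(predict(back, dat$examples, dat$features),
                   predict(fit, dat$examples, dat$features))
  expect_error(load_adrnet(tempfile()), "checkpoint")
})

test_that("training with dropout remains deterministic and predicts without it", {
  dat <- tiny_planted(n = 60, noise_sd = 0.3)
  a <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3, d_prime = 2,
              dropout = 0.3, epochs = 25, seed = 6)
  b <- adrnet(dat$examples, dat$features, tiny_vocab(), d = 3, d_prime = 2,
              dropout = 0.3, epochs = 25, seed = 6)
  expect_identical(a$params, b$params)
  # inference is deterministic (no dropout at predict time)
  expect_identical(predict(a, dat$examples, dat$features),
                   predict(a, dat$examples, dat$features))
})
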
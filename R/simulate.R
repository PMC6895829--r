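# Synthetic longitudinal MDD cohorts. Two generators are provided:
#   * generate_cohort()      -- trajectory-level simulator with planted linear
#                               and ReLU covariate effects, per-drug response
#                               effects and an interval-dependent response.
#   * generate_from_planted()-- draws one-step examples whose targets come
#                               from the forward pass of a network with known
#                               ("planted") parameters; the recovery oracle.

default_drug_names <- function(n) {
  base <- c("MIRTAZAPINE", "MILNACIPRAN", "ESCITALOPRAM", "AMITRIPTYLINE",
            "FLUOXETINE", "PAROXETINE", "SERTRALINE", "VENLAFAXINE",
            "DULOXETINE", "BUPROPION", "TRAZODONE", "VORTIOXETINE",
            "IMIPRAMINE", "CITALOPRAM")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("DRUG_%02d", seq_len(n - length(base))))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults mirror the
#' study conditions the model targets: a 121-patient cohort assessed at weeks
#' 0, 1, 4 and 8, a 14-drug antidepressant vocabulary with prescriptions of
#' one or two drugs, and the 127/20/20/20 post-selection covariate layout.
#'
#' @param n_patients Number of patients.
#' @param n_drugs Vocabulary size.
#' @param visits_schedule Week offsets of the scheduled visits.
#' @param feature_sizes Named block widths of the covariate schema.
#' @param drug_effects Per-drug HAM-D change per week (negative = the drug
#'   lowers the score). `NULL` draws them once from N(-0.6, 0.25^2) under the
#'   config seed.
#' @param feature_weights Planted per-feature linear weights on the weekly
#'   score change (concatenated across blocks). `NULL` plants a sparse set:
#'   10% of features get N(0, 0.05^2) weights.
#' @param nonlin_weight Coefficient of a planted ReLU interaction term so the
#'   response is not purely linear in the covariates.
#' @param baseline_range,baseline_mean,baseline_sd Truncated-normal intake
#'   HAM-D distribution (defaults: \[8, 40\], mean 22, sd 6 — moderate to
#'   severe depression).
#' @param pair_prob Probability that a visit's prescription is a two-drug
#'   combination rather than a single drug.
#' @param noise_sd Gaussian noise sd on each next-visit score, in HAM-D
#'   points.
#' @param missing_rate Per-block probability that a feature entry is missing;
#'   recycled over blocks.
#' @param visit_dropout Probability that a non-initial scheduled visit is
#'   skipped (0 keeps the full schedule for every patient).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 121L, n_drugs = 14L,
                       visits_schedule = c(0, 1, 4, 8),
                       feature_sizes = default_schema(),
                       drug_effects = NULL, feature_weights = NULL,
                       nonlin_weight = 0.3,
                       baseline_range = c(8, 40), baseline_mean = 22,
                       baseline_sd = 6, pair_prob = 0.3, noise_sd = 1,
                       missing_rate = 0.1, visit_dropout = 0,
                       seed = 1L) {
  stopifnot(n_patients >= 0L, n_drugs >= 1L, length(visits_schedule) >= 1L,
            all(feature_sizes >= 1L), all(missing_rate >= 0),
            all(missing_rate < 1), noise_sd >= 0,
            visit_dropout >= 0, visit_dropout < 1,
            pair_prob >= 0, pair_prob <= 1,
            !is.unsorted(visits_schedule, strictly = TRUE))
  structure(as.list(environment()), class = "sim_config")
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d patients, %d drugs, visits at weeks %s\n",
              x$n_patients, x$n_drugs,
              paste(x$visits_schedule, collapse = "/")))
  cat(sprintf("  schema %s; noise sd %.2f; missing rate %s; seed %d\n",
              paste(sprintf("%s=%d", names(x$feature_sizes),
                            x$feature_sizes), collapse = ", "),
              x$noise_sd, paste(x$missing_rate, collapse = "/"), x$seed))
  invisible(x)
}

# Demographic block: log-scaled continuous columns followed by one-hot
# categorical groups, matching how real-valued and discrete demographics are
# encoded. Other blocks are standard-normal covariates.
sim_feature_block <- function(n, p, block) {
  if (block == "demographic" && p >= 8L) {
    p_cont <- max(4L, p %/% 4L)
    cont <- matrix(log(exp(rnorm(n * p_cont, 0, 0.5)) + 0.1), n, p_cont)
    p_cat <- p - p_cont
    cols <- matrix(0, n, p_cat)
    j <- 1L
    while (j <= p_cat) {
      k <- min(sample(2:5, 1L), p_cat - j + 1L)
      lev <- sample.int(k, n, replace = TRUE)
      cols[cbind(seq_len(n), j + lev - 1L)] <- 1
      j <- j + k
    }
    cbind(cont, cols)
  } else {
    matrix(rnorm(n * p), n, p)
  }
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates HAM-D trajectories under a planted response model. Each patient
#' receives a truncated-normal baseline score and block-structured covariates;
#' at each inter-visit step the score changes by
#' `interval * (sum of prescribed drug effects + x'w + nonlin_weight *
#' relu(x'u))` plus Gaussian noise, and is clamped at 0. With all planted
#' effects and noise zero, trajectories are constant at baseline. Per-feature
#' missingness is then applied at the configured rate.
#'
#' @param config A [sim_config()] object.
#' @return List with `visits` (visit table as for [build_pairs()]),
#'   `features` (blocks with `NA` where missing), `vocabulary`, and `truth`
#'   (the planted drug effects and feature weights).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_seed(cf$seed, {
    vocabulary <- default_drug_names(cf$n_drugs)
    sizes <- cf$feature_sizes
    P <- sum(sizes)
    drug_eff <- cf$drug_effects %||% rnorm(cf$n_drugs, -0.6, 0.25)
    if (length(drug_eff) != cf$n_drugs)
      stop("drug_effects must have length n_drugs")
    w <- cf$feature_weights
    if (is.null(w)) {
      w <- numeric(P)
      live <- sample.int(P, max(1L, round(0.1 * P)))
      w[live] <- rnorm(length(live), 0, 0.05)
    }
    if (length(w) != P)
      stop("feature_weights must have length sum(feature_sizes)")
    u <- numeric(P)
    if (cf$nonlin_weight != 0) {
      live_u <- sample.int(P, max(1L, round(0.05 * P)))
      u[live_u] <- rnorm(length(live_u), 0, 0.1)
    }

    ids <- sprintf("P%03d", seq_len(cf$n_patients))
    features <- lapply(names(sizes), function(b)
      sim_feature_block(cf$n_patients, sizes[[b]], b))
    names(features) <- names(sizes)
    features <- lapply(features, function(m) {
      rownames(m) <- ids; m
    })
    Fall <- do.call(cbind, features)
    lin <- as.vector(Fall %*% w)
    nl <- cf$nonlin_weight * pmax(as.vector(Fall %*% u), 0)

    baseline <- rtruncnorm(cf$n_patients, cf$baseline_mean, cf$baseline_sd,
                           cf$baseline_range[1L], cf$baseline_range[2L])
    rows <- vector("list", cf$n_patients)
    for (i in seq_len(cf$n_patients)) {
      weeks <- cf$visits_schedule
      if (cf$visit_dropout > 0 && length(weeks) > 1L) {
        keep <- c(TRUE, runif(length(weeks) - 1L) >= cf$visit_dropout)
        weeks <- weeks[keep]
      }
      nv <- length(weeks)
      h <- numeric(nv)
      h[1L] <- baseline[i]
      drugs <- character(nv)
      for (v in seq_len(nv)) {
        k <- if (runif(1) < cf$pair_prob && cf$n_drugs >= 2L) 2L else 1L
        drugs[v] <- join_drugs(sort(vocabulary[sample.int(cf$n_drugs, k)]))
      }
      if (nv > 1L) for (v in seq_len(nv - 1L)) {
        dt <- weeks[v + 1L] - weeks[v]
        eff <- sum(drug_eff[match(parse_drugs(drugs[v]), vocabulary)])
        h[v + 1L] <- max(0, h[v] + dt * (eff + lin[i] + nl[i]) +
                              rnorm(1, 0, cf$noise_sd))
      }
      rows[[i]] <- data.frame(
        patient_id = ids[i], visit_index = seq_len(nv),
        weeks_since_prev = c(NA, diff(weeks)), hamd = h, drugs = drugs,
        stringsAsFactors = FALSE)
    }
    visits <- do.call(rbind, rows)
    rownames(visits) <- NULL

    mr <- rep_len(cf$missing_rate, length(features))
    for (bi in seq_along(features)) {
      if (mr[bi] > 0) {
        m <- features[[bi]]
        mask <- matrix(runif(length(m)) < mr[bi], nrow(m), ncol(m))
        # keep at least one donor per feature index
        for (j in which(colSums(!mask) == 0L))
          mask[sample.int(nrow(m), 1L), j] <- FALSE
        m[mask] <- NA_real_
        features[[bi]] <- m
      }
    }

    list(visits = visits, features = features, vocabulary = vocabulary,
         truth = list(drug_effects = drug_eff, feature_weights = w,
                      nonlin_weights = u))
  })
}

#' Construct a network with known (planted) parameters
#'
#' Builds an `"adrnet"` object with Gaussian random weights, rescaled so that
#' predictions over a reference input sample have a realistic next-visit
#' HAM-D location and spread. Used as a generative oracle for
#' parameter-recovery and rollout tests.
#'
#' @param schema Named covariate block widths.
#' @param vocabulary Drug name vector.
#' @param d,d_prime Representation widths.
#' @param nonlinearity Patient-layer activation.
#' @param target_mean,target_sd Desired mean and sd of predictions over the
#'   calibration sample (HAM-D points).
#' @param seed Integer seed.
#' @return An `"adrnet"` object (untrained; parameters are the ground truth).
#' @export
planted_model <- function(schema = default_schema(),
                          vocabulary = default_drug_names(14L),
                          d = 8L, d_prime = 4L, nonlinearity = "relu",
                          target_mean = 15, target_sd = 6, seed = 1L) {
  with_seed(seed, {
    p_input <- sum(schema) + 2L
    params <- init_params(p_input, d, d_prime, length(vocabulary), 0.1)
    cal <- planted_inputs(500L, schema, vocabulary, seed = seed + 1L)
    # choose biases so every hidden unit is active for 80-95% of patients:
    # rare-spike units make the planted response discontinuous in practice
    Xcal <- build_design(cal$features, cal$examples)
    A <- Xcal %*% params$W_P
    qs <- runif(d, 0.05, 0.2)
    params$b_P <- -vapply(seq_len(d), function(j)
      unname(stats::quantile(A[, j], qs[j])), numeric(1))
    obj <- structure(list(params = params, vocabulary = vocabulary,
                          schema = schema,
                          config = list(d = d, d_prime = d_prime,
                                        nonlinearity = nonlinearity,
                                        dropout = 0, l2 = 0, epochs = 0L,
                                        seed = seed),
                          n_examples = 0L),
                     class = "adrnet")
    mu <- predict(obj, cal$examples, cal$features)
    s <- sd(mu)
    if (s < 1e-8) s <- 1
    scale <- target_sd / s
    if (nonlinearity %in% c("relu", "identity")) {
      # split the calibration across layers (ReLU is positively homogeneous)
      # so no single tensor carries extreme weights
      r <- sqrt(scale)
      obj$params$W_P <- obj$params$W_P * r
      obj$params$b_P <- obj$params$b_P * r
      obj$params$E_A <- obj$params$E_A * r
      obj$params$W <- obj$params$W * r
    } else {
      obj$params$W <- obj$params$W * scale
    }
    obj$params$b <- target_mean + (obj$params$b - mean(mu)) * scale
    rownames(obj$params$E_A) <- vocabulary
    obj
  })
}

# Random patient states (features, current score, interval, prescription)
# matching a schema; shared by planted_model() and generate_from_planted().
planted_inputs <- function(n, schema, vocabulary, pair_prob = 0.3,
                           seed = NULL) {
  with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(n))
    features <- lapply(names(schema), function(b)
      sim_feature_block(n, schema[[b]], b))
    names(features) <- names(schema)
    features <- lapply(features, function(m) { rownames(m) <- ids; m })
    drugs <- vapply(seq_len(n), function(i) {
      k <- if (runif(1) < pair_prob && length(vocabulary) >= 2L) 2L else 1L
      join_drugs(sort(vocabulary[sample.int(length(vocabulary), k)]))
    }, character(1))
    examples <- data.frame(
      patient_id = ids,
      hamd_now = rtruncnorm(n, 22, 6, 8, 40),
      interval = sample(c(1, 3, 4), n, replace = TRUE),
      drugs = drugs, stringsAsFactors = FALSE)
    list(examples = examples, features = features)
  })
}

#' Draw one-step training examples from a planted network
#'
#' Samples random patient states and computes targets by the planted model's
#' forward pass plus Gaussian noise. With `noise_sd = 0` the targets equal
#' the planted predictions exactly, so a matching architecture can reach zero
#' training error.
#'
#' @param model A planted (or fitted) `"adrnet"` object.
#' @param n Number of examples.
#' @param noise_sd Gaussian noise sd added to the targets.
#' @param pair_prob Probability of a two-drug prescription.
#' @param seed Integer seed.
#' @return List with `examples` (including the `hamd_next` targets),
#'   `features`, and the generating `model`.
#' @export
generate_from_planted <- function(model, n, noise_sd = 0.5, pair_prob = 0.3,
                                  seed = 1L) {
  stopifnot(inherits(model, "adrnet"), n >= 0L)
  if (n == 0L) {
    inp <- planted_inputs(0L, model$schema, model$vocabulary)
    inp$examples$hamd_next <- numeric(0)
    return(list(examples = inp$examples, features = inp$features,
                model = model))
  }
  inp <- planted_inputs(n, model$schema, model$vocabulary, pair_prob,
                        seed = seed)
  y <- predict(model, inp$examples, inp$features) +
    with_seed(seed + 1L, rnorm(n, 0, noise_sd))
  inp$examples$hamd_next <- y
  list(examples = inp$examples, features = inp$features, model = model)
}
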
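# Network architecture
# --------------------
# X_P = [demographic; biomarkers; variants; methylation; H; dT]   (length P)
# V_P = sigma(X_P W_P + b_P)                                      (length d)
# V_A = sum of embedding rows E_A[j, ] over prescribed drugs j    (length d')
# Yhat = [V_P; V_A] . W + b
# trained by minibatch Adam on MSE with inverted dropout on V_P and an L2
# penalty on W_P, E_A and W (not on biases).

#' Assemble the patient-layer input vector
#'
#' Concatenates the covariate blocks with the current HAM-D score and the
#' interval to the next visit, in the fixed order demographic, biomarkers,
#' variants, methylation, H, dT. Under the default schema
#' (127 + 20 + 20 + 20 + 1 + 1) the result has length 189.
#'
#' @param features Named list of numeric vectors, one per covariate block, in
#'   the schema's block order (e.g. the row of each block matrix for one
#'   patient).
#' @param hamd_now Current HAM-D score (single non-negative number).
#' @param interval Weeks until the next visit (single positive number).
#' @param schema Named integer vector of expected block widths; defaults to
#'   the widths of `features`.
#' @return Numeric vector of length `sum(schema) + 2`.
#' @export
assemble_input <- function(features, hamd_now, interval, schema = NULL) {
  stopifnot(is.list(features))
  if (is.null(schema)) schema <- vapply(features, length, integer(1))
  if (!identical(names(features), names(schema)))
    stop("feature blocks must be named ", paste(names(schema), collapse = "/"))
  for (b in names(schema))
    if (length(features[[b]]) != schema[[b]])
      stop("block '", b, "' has length ", length(features[[b]]),
           "; schema expects ", schema[[b]])
  x <- c(unlist(features, use.names = FALSE), hamd_now, interval)
  if (any(!is.finite(x))) stop("non-finite values in assembled input")
  x
}

# Design matrix for a set of examples: one row per example,
# [blocks at the example's patient; hamd_now; interval].
build_design <- function(features, examples) {
  check_features(features)
  F <- do.call(cbind, features)
  idx <- match(examples$patient_id, rownames(F))
  if (anyNA(idx))
    stop("examples reference unknown patient_id(s): ",
         paste(unique(examples$patient_id[is.na(idx)]), collapse = ", "))
  X <- cbind(F[idx, , drop = FALSE], examples$hamd_now, examples$interval)
  dimnames(X) <- NULL
  if (anyNA(X))
    stop("design matrix contains NA; impute features first (impute_missing)")
  X
}

nonlin_fun <- function(name) {
  switch(name,
    relu     = list(f = function(z) pmax(z, 0), df = function(z, v) (z > 0) * 1),
    tanh     = list(f = tanh,                   df = function(z, v) 1 - v^2),
    sigmoid  = list(f = function(z) 1 / (1 + exp(-z)),
                    df = function(z, v) v * (1 - v)),
    identity = list(f = identity,               df = function(z, v) 1),
    stop("unknown nonlinearity: ", name))
}

init_params <- function(p_input, d, d_prime, n_drugs, sd = 0.1) {
  list(W_P = matrix(rnorm(p_input * d, 0, sd), p_input, d),
       b_P = rnorm(d, 0, sd),
       E_A = matrix(rnorm(n_drugs * d_prime, 0, sd), n_drugs, d_prime),
       W   = rnorm(d + d_prime, 0, sd),
       b   = rnorm(1, 0, sd))
}

#' Patient representation vector
#'
#' The hidden-layer activation `sigma(X_P W_P + b_P)` summarising a patient's
#' covariates and current state.
#'
#' @param X Patient input vector (length `nrow(params$W_P)`) or a matrix with
#'   one such row per patient.
#' @param params Model parameter list with elements `W_P` and `b_P`.
#' @param nonlinearity One of `"relu"`, `"tanh"`, `"sigmoid"`, `"identity"`.
#' @return Matrix of representation vectors, one row per input row.
#' @export
patient_repr <- function(X, params, nonlinearity = "relu") {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (any(!is.finite(X))) stop("non-finite values in patient input")
  if (ncol(X) != nrow(params$W_P))
    stop("input width ", ncol(X), " does not match W_P (",
         nrow(params$W_P), " rows)")
  nl <- nonlin_fun(nonlinearity)
  Z <- sweep(X %*% params$W_P, 2L, params$b_P, `+`)
  nl$f(Z)
}

#' Prescription representation vector
#'
#' A prescription's representation is the sum of the embedding rows of its
#' drugs; a single-drug prescription maps to that drug's embedding row.
#'
#' @param prescription Character vector of drug names (or a single
#'   semicolon-joined string); must be non-empty and within the vocabulary.
#' @param E_A Drug embedding matrix with one row per vocabulary entry, in
#'   vocabulary order (rownames are the drug names).
#' @return Numeric vector of length `ncol(E_A)`.
#' @export
prescription_repr <- function(prescription, E_A) {
  if (length(prescription) == 1L && grepl(";", prescription, fixed = TRUE))
    prescription <- parse_drugs(prescription)
  if (length(prescription) == 0L)
    stop("empty prescription: at least one drug is required")
  vocab <- rownames(E_A)
  if (is.null(vocab)) stop("E_A must carry drug names as rownames")
  unknown <- setdiff(prescription, vocab)
  if (length(unknown))
    stop("unknown drug name(s): ", paste(unknown, collapse = ", "))
  colSums(E_A[match(prescription, vocab), , drop = FALSE])
}

#' Mean squared error
#'
#' @param y,yhat Numeric vectors of equal positive length.
#' @return `mean((y - yhat)^2)`.
#' @export
mse_loss <- function(y, yhat) {
  if (length(y) == 0L) stop("mse_loss is undefined for empty input")
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  mean((y - yhat)^2)
}

# Forward pass for a batch. Returns intermediates needed for the backward
# pass. `drop_mask` (n x d in {0,1}) enables inverted dropout on V_P.
forward_pass <- function(params, X, M, nonlinearity, drop_mask = NULL,
                         dropout = 0) {
  nl <- nonlin_fun(nonlinearity)
  Z <- sweep(X %*% params$W_P, 2L, params$b_P, `+`)
  V <- nl$f(Z)
  Vd <- if (is.null(drop_mask)) V else V * drop_mask / (1 - dropout)
  VA <- M %*% params$E_A
  H <- cbind(Vd, VA)
  yhat <- as.vector(H %*% params$W + params$b)
  list(Z = Z, V = V, Vd = Vd, VA = VA, H = H, yhat = yhat)
}

# Loss (MSE + L2 penalty) and analytic gradients for a batch.
loss_and_grads <- function(params, X, M, y, nonlinearity = "relu",
                           l2 = 0, drop_mask = NULL, dropout = 0) {
  n <- length(y)
  d <- ncol(params$W_P)
  dp <- ncol(params$E_A)
  nl <- nonlin_fun(nonlinearity)
  fw <- forward_pass(params, X, M, nonlinearity, drop_mask, dropout)
  resid <- fw$yhat - y
  loss <- mean(resid^2) +
    l2 * (sum(params$W_P^2) + sum(params$E_A^2) + sum(params$W^2))
  r <- 2 * resid / n
  gW <- as.vector(crossprod(fw$H, r)) + 2 * l2 * params$W
  gb <- sum(r)
  dH <- tcrossprod(r, params$W)            # n x (d + d')
  dVd <- dH[, seq_len(d), drop = FALSE]
  dV <- if (is.null(drop_mask)) dVd else dVd * drop_mask / (1 - dropout)
  dZ <- dV * nl$df(fw$Z, fw$V)
  gW_P <- crossprod(X, dZ) + 2 * l2 * params$W_P
  gb_P <- colSums(dZ)
  dVA <- dH[, d + seq_len(dp), drop = FALSE]
  gE_A <- crossprod(M, dVA) + 2 * l2 * params$E_A
  list(loss = loss,
       grads = list(W_P = gW_P, b_P = gb_P, E_A = gE_A, W = gW, b = gb),
       yhat = fw$yhat)
}

# Central-difference gradient of the batch loss w.r.t. every parameter;
# used by the gradient-check tests as the independent numerical oracle.
numeric_grads <- function(params, X, M, y, nonlinearity = "relu", l2 = 0,
                          h = 1e-5) {
  loss_at <- function(p) {
    fw <- forward_pass(p, X, M, nonlinearity)
    mean((fw$yhat - y)^2) + l2 * (sum(p$W_P^2) + sum(p$E_A^2) + sum(p$W^2))
  }
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]]
    for (i in seq_along(g)) {
      pp <- params; pm <- params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

#' Fit the antidepressant-response prediction network
#'
#' Trains the two-branch network on one-step visit transitions: a patient
#' representation layer embeds the covariates plus current HAM-D score and
#' visit interval, a drug-embedding layer represents the prescription as the
#' sum of its drugs' embedding vectors, and a linear head predicts the
#' next-visit HAM-D score. Parameters are Gaussian-initialised and optimised
#' by minibatch Adam on mean squared error, with inverted dropout on the
#' patient representation and an L2 penalty on the weight matrices.
#'
#' @param examples Training examples as returned by [build_pairs()]: columns
#'   `patient_id`, `hamd_now`, `interval`, `drugs`, `hamd_next`.
#' @param features Imputed covariate blocks (named list of patient-by-feature
#'   matrices; no `NA`).
#' @param vocabulary Character vector of drug names; its order fixes the
#'   embedding rows.
#' @param d Width of the patient representation vector.
#' @param d_prime Width of the drug embedding vectors.
#' @param nonlinearity Activation of the patient layer (`"relu"` default;
#'   `"tanh"`, `"sigmoid"`, `"identity"` also supported).
#' @param dropout Dropout rate on the patient representation during training.
#' @param l2 L2 penalty weight on `W_P`, `E_A` and `W`.
#' @param learning_rate,batch_size,epochs Adam step size, minibatch size and
#'   number of passes over the data.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = constant;
#'   values just below 1 anneal the step size so the optimiser can settle).
#' @param init_sd Standard deviation of the Gaussian parameter initialisation.
#' @param seed Integer seed controlling initialisation, shuffling and dropout.
#' @param verbose Print the epoch loss every 50 epochs.
#' @return An object of class `"adrnet"`: a list with the trained `params`
#'   (`W_P`, `b_P`, `E_A`, `W`, `b`), the `vocabulary`, covariate `schema`,
#'   `config` (all hyperparameters), per-epoch training `loss`, and fitted
#'   values/residuals on the training set. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()` and
#'   `simulate()`.
#' @examples
#' sim <- generate_cohort(sim_config(n_patients = 30, seed = 1))
#' feats <- impute_missing(sim$features, seed = 1)
#' ex <- build_pairs(sim$visits)
#' fit <- adrnet(ex, feats, sim$vocabulary, d = 8, d_prime = 4,
#'               epochs = 20, seed = 1)
#' fit
#' @export
adrnet <- function(examples, features, vocabulary,
                   d = 32L, d_prime = 8L, nonlinearity = "relu",
                   dropout = 0.1, l2 = 1e-4, learning_rate = 0.001,
                   batch_size = 16L, epochs = 300L, lr_decay = 1,
                   init_sd = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(d >= 1L, d_prime >= 1L, dropout >= 0, dropout < 1, l2 >= 0,
            epochs >= 0L, batch_size >= 1L)
  if (nrow(examples) == 0L) stop("training set is empty")
  schema <- check_features(features)
  X <- build_design(features, examples)
  M <- drug_incidence(examples$drugs, vocabulary)
  y <- examples$hamd_next
  p_input <- ncol(X)
  n <- nrow(X)
  config <- list(d = as.integer(d), d_prime = as.integer(d_prime),
                 nonlinearity = nonlinearity, dropout = dropout, l2 = l2,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_decay = lr_decay,
                 init_sd = init_sd, seed = as.integer(seed))

  with_seed(seed, {
    params <- init_params(p_input, d, d_prime, length(vocabulary), init_sd)
    ad_m <- rapply(params, function(x) x * 0, how = "replace")
    ad_v <- ad_m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    loss_hist <- numeric(epochs)
    lr_ep <- learning_rate
    if (epochs > 0L) for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, n)]
        mask <- if (dropout > 0)
          matrix(rbinom(length(rows) * d, 1L, 1 - dropout),
                 length(rows), d)
        else NULL
        lg <- loss_and_grads(params, X[rows, , drop = FALSE],
                             M[rows, , drop = FALSE], y[rows],
                             nonlinearity, l2, mask, dropout)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        t_step <- t_step + 1L
        for (nm in names(params)) {
          g <- lg$grads[[nm]]
          ad_m[[nm]] <- b1 * ad_m[[nm]] + (1 - b1) * g
          ad_v[[nm]] <- b2 * ad_v[[nm]] + (1 - b2) * g^2
          mhat <- ad_m[[nm]] / (1 - b1^t_step)
          vhat <- ad_v[[nm]] / (1 - b2^t_step)
          params[[nm]] <- params[[nm]] -
            lr_ep * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + lg$loss * length(rows)
      }
      loss_hist[ep] <- ep_loss / n
      lr_ep <- lr_ep * lr_decay
      if (verbose && ep %% 50L == 0L)
        message(sprintf("epoch %d  loss %.4f", ep, loss_hist[ep]))
    }
    rownames(params$E_A) <- vocabulary

    fw <- forward_pass(params, X, M, nonlinearity)
    structure(list(params = params, vocabulary = vocabulary, schema = schema,
                   config = config, loss = loss_hist,
                   fitted.values = fw$yhat, residuals = y - fw$yhat,
                   y = y, n_examples = n, call = match.call()),
              class = "adrnet")
  })
}

# Raw batch prediction from a fitted (or planted) model.
predict_raw <- function(object, X, M) {
  fw <- forward_pass(object$params, X, M, object$config$nonlinearity)
  fw$yhat
}

#' Predict next-visit HAM-D scores
#'
#' Deterministic forward pass (dropout off). Predictions are raw regression
#' output by default; `clamp = TRUE` truncates them to the HAM-D 17 range
#' \[0, 52\].
#'
#' @param object A fitted `"adrnet"` model.
#' @param examples Data frame with columns `patient_id`, `hamd_now`,
#'   `interval`, `drugs`.
#' @param features Imputed covariate blocks covering every referenced patient.
#' @param clamp Truncate predictions to \[0, 52\]?
#' @param ... Unused.
#' @return Numeric vector of predicted scores.
#' @export
predict.adrnet <- function(object, examples, features, clamp = FALSE, ...) {
  X <- build_design(features, examples)
  M <- drug_incidence(examples$drugs, object$vocabulary)
  yhat <- predict_raw(object, X, M)
  if (clamp) yhat <- pmin(pmax(yhat, 0), 52)
  yhat
}

#' Simulate next-visit scores from a model
#'
#' Draws targets from the model's forward pass plus Gaussian observation
#' noise; used both as a generic `simulate()` method and as the generative
#' oracle behind [generate_from_planted()].
#'
#' @param object A fitted or planted `"adrnet"` model.
#' @param nsim Number of simulated replicates.
#' @param seed Integer seed.
#' @param examples,features As for [predict.adrnet()].
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated `hamd_next` values.
#' @export
simulate.adrnet <- function(object, nsim = 1, seed = NULL,
                            examples, features, noise_sd = 0, ...) {
  mu <- predict(object, examples, features)
  with_seed(seed, {
    out <- as.data.frame(lapply(seq_len(nsim), function(i)
      mu + rnorm(length(mu), 0, noise_sd)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Cross-validated hyperparameter search
#'
#' Evaluates every row of a hyperparameter grid by k-fold cross-validated
#' RMSE on the training set and returns the winning configuration. Ties are
#' broken by smaller `d + d_prime`, then smaller dropout, then smaller l2.
#'
#' @param examples,features,vocabulary As for [adrnet()].
#' @param grid Data frame whose columns are `adrnet()` hyperparameters
#'   (`d`, `d_prime`, `dropout`, `l2`, ...); one row per candidate.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for fold assignment and training.
#' @param ... Fixed arguments passed on to [adrnet()] (e.g. `epochs`).
#' @return List with `best` (named list of the winning hyperparameters) and
#'   `results` (the grid with a `cv_rmse` column).
#' @export
tune_adrnet <- function(examples, features, vocabulary, grid, k = 5L,
                        seed = 1L, ...) {
  if (nrow(grid) == 0L) stop("hyperparameter grid is empty")
  n <- nrow(examples)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than examples")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  fixed <- list(...)
  cv_rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- examples[fold != f, , drop = FALSE]
      te <- examples[fold == f, , drop = FALSE]
      args <- c(list(examples = tr, features = features,
                     vocabulary = vocabulary, seed = seed),
                as.list(grid[g, , drop = FALSE]), fixed)
      bs <- args$batch_size %||% 16L
      if (nrow(tr) < bs) {
        warning("fold smaller than batch size; clipping batch to ", nrow(tr))
        args$batch_size <- nrow(tr)
      }
      fit <- do.call(adrnet, args)
      errs[f] <- rmse(te$hamd_next, predict(fit, te, features))
    }
    cv_rmse[g] <- mean(errs)
  }
  results <- cbind(grid, cv_rmse = cv_rmse)
  size <- grid$d %||% 0 + grid$d_prime %||% 0
  ord <- order(cv_rmse, size,
               grid$dropout %||% rep(0, nrow(grid)),
               grid$l2 %||% rep(0, nrow(grid)))
  list(best = as.list(grid[ord[1L], , drop = FALSE]), results = results)
}
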
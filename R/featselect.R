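# Two-step feature selection: a missingness filter, then a nested
# cross-validated elastic-net protocol that keeps, per covariate block, the
# 10 most-positive and 10 most-negative averaged coefficients.

#' Missingness filter
#'
#' Drops features that are missing in more than `threshold` of patients
#' (strictly more: a feature missing in exactly 30% of patients survives the
#' default filter). Kept indices preserve their original order.
#'
#' @param block Numeric patient-by-feature matrix with `NA` marking missing
#'   entries, or a logical missingness mask of the same shape.
#' @param threshold Missing-fraction cutoff in (0, 1); default 0.3.
#' @return Integer vector of kept feature indices.
#' @export
missingness_filter <- function(block, threshold = 0.3) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must be in (0, 1)")
  if (is.null(dim(block)) || nrow(block) == 0L || ncol(block) == 0L)
    stop("empty feature block")
  frac <- if (is.logical(block)) colMeans(block) else colMeans(is.na(block))
  which(frac <= threshold)
}

#' Exact elastic-net fit
#'
#' Minimises the unnormalised penalised least-squares objective
#' \deqn{||Y - X\beta||^2 + \lambda_2 ||\beta||^2 + \lambda_1 ||\beta||_1}
#' (no intercept, no internal standardisation) by cyclic coordinate descent.
#' With both penalties zero this is ordinary least squares; with
#' `lambda2 = 0` it is the lasso in its unnormalised parameterisation, whose
#' single-feature solution is the soft-thresholded OLS coefficient
#' `S(x'y, lambda1/2) / x'x`.
#'
#' @param X Design matrix (no missing values, at least one column).
#' @param Y Response vector, `length(Y) == nrow(X)`.
#' @param lambda1 Non-negative L1 penalty weight.
#' @param lambda2 Non-negative L2 penalty weight.
#' @param tol,maxit Coordinate-descent convergence tolerance (max absolute
#'   coefficient change per sweep) and sweep cap.
#' @return Numeric coefficient vector, one per column of `X`.
#' @export
elastic_net_fit <- function(X, Y, lambda1 = 0, lambda2 = 0,
                            tol = 1e-12, maxit = 100000L) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("degenerate design matrix: zero columns")
  if (nrow(X) != length(Y)) stop("nrow(X) must equal length(Y)")
  if (anyNA(X) || anyNA(Y)) stop("X and Y must not contain NA")
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  beta <- elnet_gram_cd(crossprod(X), as.vector(crossprod(X, Y)),
                        lambda1, lambda2, maxit = maxit, tol = tol)
  names(beta) <- colnames(X)
  beta
}

# Eq-objective value; used by tests and select_block diagnostics.
elnet_objective <- function(X, Y, beta, lambda1, lambda2) {
  sum((Y - X %*% beta)^2) + lambda2 * sum(beta^2) + lambda1 * sum(abs(beta))
}

#' Default elastic-net hyperparameter grid
#'
#' A 10 x 10 logarithmic grid over \[1e-4, 1e2\] for both penalty weights.
#'
#' @param n_lambda1,n_lambda2 Grid resolution per penalty.
#' @param range Common logarithmic range.
#' @return Data frame with columns `lambda1`, `lambda2`.
#' @export
elastic_net_grid <- function(n_lambda1 = 10L, n_lambda2 = 10L,
                             range = c(1e-4, 1e2)) {
  l1 <- 10^seq(log10(range[1L]), log10(range[2L]), length.out = n_lambda1)
  l2 <- 10^seq(log10(range[1L]), log10(range[2L]), length.out = n_lambda2)
  expand.grid(lambda1 = l1, lambda2 = l2, KEEP.OUT.ATTRS = FALSE)
}

#' Data-driven block feature selection
#'
#' Implements the nested elastic-net selection protocol for one covariate
#' block. The rows are split into five outer subsets; for each subset, the
#' penalty weights are chosen by 10-fold cross-validated held-out MSE on the
#' remaining four subsets and the model is refit on those four subsets; the
#' per-feature coefficients from the five fits are averaged, and the 10 most
#' positive plus 10 most negative averaged coefficients are selected (ties at
#' the rank boundary broken by ascending feature index).
#'
#' In the default `"per_feature"` mode each candidate feature is fit in its
#' own model whose design is that feature concatenated with the multi-hot
#' encoded drug vector, mirroring a marginal screen; `"joint"` fits the whole
#' block plus drug encoding in a single model. Feature columns are
#' standardised to zero mean and unit variance and the response is centred
#' before fitting; coefficients are reported on the standardised scale.
#'
#' @param block Numeric patient/sample-by-feature matrix (>= 20 columns).
#' @param drugs Multi-hot drug encoding matrix with matching rows (may have
#'   zero columns to select without drug adjustment).
#' @param response Numeric response: the first-to-last HAM-D change.
#' @param grid Hyperparameter grid, as from [elastic_net_grid()].
#' @param n_outer,n_folds Outer subsets and inner CV folds.
#' @param method `"per_feature"` (default) or `"joint"`.
#' @param block_name Label carried into the result.
#' @param seed Integer seed for the outer/inner fold assignment.
#' @return Object of class `"selection_result"`: list with `block`,
#'   `coefficients` (averaged, one per feature), `selected` (20 indices:
#'   10 most positive then 10 most negative), `positive`, `negative`,
#'   `method`.
#' @export
select_block <- function(block, drugs, response, grid = elastic_net_grid(),
                         n_outer = 5L, n_folds = 10L,
                         method = c("per_feature", "joint"),
                         block_name = "block", seed = 1L) {
  method <- match.arg(method)
  block <- as.matrix(block)
  drugs <- as.matrix(drugs)
  n <- nrow(block)
  p <- ncol(block)
  if (p < 20L)
    stop("block has ", p, " features; at least 20 are required to select 20")
  if (nrow(drugs) != n || length(response) != n)
    stop("block, drugs and response must have matching rows")
  if (n < n_outer * n_folds)
    stop("need at least ", n_outer * n_folds, " rows for the nested ",
         n_outer, "x", n_folds, " protocol; got ", n)

  # standardise features, centre response
  mu <- colMeans(block)
  sdv <- apply(block, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  Xb <- scale(block, center = mu, scale = sdv)
  y <- response - mean(response)

  outer <- with_seed(seed, sample(rep_len(seq_len(n_outer), n)))
  coefs <- matrix(NA_real_, n_outer, p)
  l1g <- grid$lambda1
  l2g <- grid$lambda2

  for (s in seq_len(n_outer)) {
    tr <- which(outer != s)
    m <- length(tr)
    fold <- with_seed(seed + s, sample(rep_len(seq_len(n_folds), m)))
    if (method == "joint") {
      A <- cbind(Xb[tr, , drop = FALSE], drugs[tr, , drop = FALSE])
      ytr <- y[tr]
      cvmse <- rep(0, nrow(grid))
      for (f in seq_len(n_folds)) {
        inn <- fold != f
        Atr <- A[inn, , drop = FALSE]; Ate <- A[!inn, , drop = FALSE]
        XtX <- crossprod(Atr); Xty <- as.vector(crossprod(Atr, ytr[inn]))
        B <- elnet_gram_path(XtX, Xty, l1g, l2g)
        res <- Ate %*% B - ytr[!inn]
        cvmse <- cvmse + colMeans(res^2) / n_folds
      }
      best <- which.min(cvmse)
      beta <- elastic_net_fit(A, ytr, l1g[best], l2g[best])
      coefs[s, ] <- beta[seq_len(p)]
    } else {
      coefs[s, ] <- per_feature_coefs(Xb[tr, , drop = FALSE],
                                      drugs[tr, , drop = FALSE], y[tr],
                                      fold, n_folds, l1g, l2g)
    }
  }

  avg <- colMeans(coefs)
  names(avg) <- colnames(block) %||% paste0("f", seq_len(p))
  n_pos <- sum(avg > 0)
  n_neg <- sum(avg < 0)
  if (n_pos < 10L || n_neg < 10L)
    stop("cannot select 10 positive and 10 negative features: block has ",
         n_pos, " positive and ", n_neg, " negative averaged coefficients")
  pos <- order(-avg, seq_len(p))[1:10]
  neg <- order(avg, seq_len(p))[1:10]
  structure(list(block = block_name, coefficients = avg,
                 selected = c(pos, neg), positive = pos, negative = neg,
                 method = method, n_outer = n_outer, n_folds = n_folds),
            class = "selection_result")
}

# Per-feature nested CV coefficients on one outer-training set, computed in
# the Gram domain so the grid search costs O(p^2) per fit regardless of n.
per_feature_coefs <- function(Xb, D, y, fold, n_folds, l1g, l2g) {
  p <- ncol(Xb)
  q <- ncol(D)
  m <- nrow(Xb)
  # totals over the outer-training set
  DtD_t <- crossprod(D); Dty_t <- as.vector(crossprod(D, y))
  FtF_t <- colSums(Xb^2); FtD_t <- crossprod(Xb, D)
  Fty_t <- as.vector(crossprod(Xb, y)); yty_t <- sum(y^2)
  # per-fold pieces
  fold_parts <- lapply(seq_len(n_folds), function(f) {
    i <- fold == f
    list(DtD = crossprod(D[i, , drop = FALSE]),
         Dty = as.vector(crossprod(D[i, , drop = FALSE], y[i])),
         FtF = colSums(Xb[i, , drop = FALSE]^2),
         FtD = crossprod(Xb[i, , drop = FALSE], D[i, , drop = FALSE]),
         Fty = as.vector(crossprod(Xb[i, , drop = FALSE], y[i])),
         yty = sum(y[i]^2), n = sum(i))
  })
  ng <- length(l1g)
  out <- numeric(p)
  for (j in seq_len(p)) {
    cvmse <- rep(0, ng)
    for (f in seq_len(n_folds)) {
      fp <- fold_parts[[f]]
      # train Gram = total - fold
      XtX <- rbind(c(FtF_t[j] - fp$FtF[j], FtD_t[j, ] - fp$FtD[j, ]),
                   cbind(FtD_t[j, ] - fp$FtD[j, ], DtD_t - fp$DtD))
      Xty <- c(Fty_t[j] - fp$Fty[j], Dty_t - fp$Dty)
      B <- elnet_gram_path(XtX, Xty, l1g, l2g)
      XtX_te <- rbind(c(fp$FtF[j], fp$FtD[j, ]),
                      cbind(fp$FtD[j, ], fp$DtD))
      Xty_te <- c(fp$Fty[j], fp$Dty)
      mse <- (fp$yty - 2 * as.vector(crossprod(B, Xty_te)) +
                colSums(B * (XtX_te %*% B))) / fp$n
      cvmse <- cvmse + mse / n_folds
    }
    best <- which.min(cvmse)
    XtX <- rbind(c(FtF_t[j], FtD_t[j, ]), cbind(FtD_t[j, ], DtD_t))
    Xty <- c(Fty_t[j], Dty_t)
    beta <- elnet_gram_cd(XtX, Xty, l1g[best], l2g[best])
    out[j] <- beta[1L]
  }
  out
}

#' @method print selection_result
#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection (%s, %s): %d features scored\n",
              x$block, x$method, length(x$coefficients)))
  cat("  selected (10 most positive):",
      paste(x$positive, collapse = " "), "\n")
  cat("  selected (10 most negative):",
      paste(x$negative, collapse = " "), "\n")
  invisible(x)
}

#' Run the full feature-selection pipeline on a cohort
#'
#' Applies the missingness filter and the elastic-net block selection to each
#' non-demographic covariate block of a cohort; the demographic block is kept
#' unchanged, as demographics bypass data-driven selection. The response is
#' each patient's last-minus-first HAM-D change; the drug encoding is the
#' multi-hot union of every drug the patient received.
#'
#' @param cohort List with `visits`, `features`, `vocabulary`.
#' @param threshold Missingness cutoff for the first step.
#' @param seed Integer seed.
#' @param ... Passed on to [select_block()].
#' @return List with `features` (reduced, imputed blocks), `selection`
#'   (per-block `"selection_result"`), `kept` (per-block missingness-filter
#'   indices).
#' @export
select_features <- function(cohort, threshold = 0.3, seed = 1L, ...) {
  visits <- check_visits(cohort$visits)
  cases <- remission_cases(visits)
  ids <- cases$patient_id
  delta <- cases$hamd_last - cases$hamd_first
  drug_union <- vapply(ids, function(pid) {
    join_drugs(sort(unique(unlist(lapply(
      visits$drugs[visits$patient_id == pid], parse_drugs)))))
  }, character(1))
  D <- drug_incidence(drug_union, cohort$vocabulary)

  kept <- list(); selection <- list(); out_features <- list()
  imputed <- impute_missing(cohort$features, seed = seed)
  for (b in names(cohort$features)) {
    if (b == "demographic") {
      out_features[[b]] <- imputed[[b]]
      next
    }
    ki <- missingness_filter(cohort$features[[b]], threshold)
    kept[[b]] <- ki
    if (length(ki) <= 20L) {
      # already at (or below) the target cardinality: nothing to select
      out_features[[b]] <- imputed[[b]][, ki, drop = FALSE]
      next
    }
    blk <- imputed[[b]][ids, ki, drop = FALSE]
    sel <- select_block(blk, D, delta, block_name = b, seed = seed, ...)
    selection[[b]] <- sel
    out_features[[b]] <- imputed[[b]][, ki[sel$selected], drop = FALSE]
  }
  list(features = out_features, selection = selection, kept = kept)
}
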
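#' @method print adrnet
#' @export
print.adrnet <- function(x, ...) {
  cfg <- x$config
  cat("Antidepressant-response prediction network\n")
  cat(sprintf("  patient layer: %d -> %d (%s), drug embedding: %d x %d\n",
              sum(x$schema) + 2L, cfg$d, cfg$nonlinearity,
              length(x$vocabulary), cfg$d_prime))
  cat(sprintf("  trained %d epochs on %d examples", cfg$epochs, x$n_examples))
  if (cfg$epochs > 0L)
    cat(sprintf("; final training MSE %.4f", x$loss[length(x$loss)]))
  cat("\n")
  invisible(x)
}

#' @method summary adrnet
#' @export
summary.adrnet <- function(object, ...) {
  r <- object$residuals
  out <- list(config = object$config, schema = object$schema,
              n_examples = object$n_examples,
              vocabulary = object$vocabulary,
              train_rmse = sqrt(mean(r^2)),
              train_r_squared = r_squared(object$y, object$fitted.values),
              final_loss = if (object$config$epochs > 0)
                object$loss[length(object$loss)] else NA_real_,
              residual_summary = summary(r))
  class(out) <- "summary.adrnet"
  out
}

#' @method print summary.adrnet
#' @export
print.summary.adrnet <- function(x, ...) {
  cat("Antidepressant-response prediction network\n\n")
  cat(sprintf("Covariate schema: %s (+ HAM-D + interval)\n",
              paste(sprintf("%s=%d", names(x$schema), x$schema),
                    collapse = ", ")))
  cat(sprintf("Drug vocabulary:  %d antidepressants\n",
              length(x$vocabulary)))
  cfg <- x$config
  cat(sprintf("Hyperparameters:  d=%d d'=%d %s dropout=%.2f l2=%g lr=%g batch=%d epochs=%d\n",
              cfg$d, cfg$d_prime, cfg$nonlinearity, cfg$dropout, cfg$l2,
              cfg$learning_rate, cfg$batch_size, cfg$epochs))
  cat(sprintf("\nTraining fit on %d examples: RMSE %.4f, R-squared %.4f\n",
              x$n_examples, x$train_rmse, x$train_r_squared))
  cat("\nResiduals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.adrnet <- function(object, ...) object$params

#' @export
fitted.adrnet <- function(object, ...) object$fitted.values

#' @export
residuals.adrnet <- function(object, ...) object$residuals

#' Training diagnostics plot
#'
#' Plots the per-epoch training loss and, alongside it, observed versus
#' fitted next-visit HAM-D scores on the training set.
#'
#' @param x A fitted `"adrnet"` model.
#' @param which `1` = loss curve, `2` = observed vs fitted, `1:2` = both.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.adrnet <- function(x, which = 1:2, ...) {
  if (1 %in% which && x$config$epochs > 0) {
    plot(seq_along(x$loss), x$loss, type = "l", xlab = "epoch",
         ylab = "training loss (MSE + penalty)", main = "Training loss", ...)
  }
  if (2 %in% which) {
    plot(x$fitted.values, x$y, xlab = "fitted HAM-D", ylab = "observed HAM-D",
         main = "Observed vs fitted", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Save and load a fitted model
#'
#' A checkpoint is a directory with a JSON header (`model.json`: architecture,
#' hyperparameters, vocabulary, covariate schema) and a flat CSV weight table
#' (`weights.csv`: tensor name, row, column, value) written with 17
#' significant digits so that the load/save round trip is exact at 64-bit
#' float precision.
#'
#' @param object A fitted `"adrnet"` model.
#' @param dir Checkpoint directory (created if absent).
#' @return `save_adrnet()` invisibly returns `dir`; `load_adrnet()` returns
#'   the restored `"adrnet"` object.
#' @export
save_adrnet <- function(object, dir) {
  stopifnot(inherits(object, "adrnet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(package = "adrnet", format = 1L,
                 config = object$config,
                 schema = as.list(object$schema),
                 vocabulary = object$vocabulary,
                 n_examples = object$n_examples)
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rows <- do.call(rbind, lapply(names(object$params), function(nm) {
    p <- object$params[[nm]]
    if (is.matrix(p)) {
      data.frame(tensor = nm, row = as.vector(row(p)),
                 col = as.vector(col(p)),
                 value = sprintf("%.17g", as.vector(p)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(tensor = nm, row = seq_along(p), col = 1L,
                 value = sprintf("%.17g", p), stringsAsFactors = FALSE)
    }
  }))
  write.csv(rows, file.path(dir, "weights.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' @rdname save_adrnet
#' @export
load_adrnet <- function(dir) {
  hf <- file.path(dir, "model.json")
  wf <- file.path(dir, "weights.csv")
  if (!file.exists(hf) || !file.exists(wf))
    stop("not a model checkpoint directory: ", dir)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  w <- read.csv(wf, stringsAsFactors = FALSE,
                colClasses = c(value = "character"))
  w$value <- as.numeric(w$value)
  schema <- unlist(header$schema)
  cfg <- header$config
  p_input <- sum(schema) + 2L
  n_drugs <- length(header$vocabulary)
  shapes <- list(W_P = c(p_input, cfg$d), b_P = c(cfg$d, 1L),
                 E_A = c(n_drugs, cfg$d_prime),
                 W = c(cfg$d + cfg$d_prime, 1L), b = c(1L, 1L))
  params <- list()
  for (nm in names(shapes)) {
    ww <- w[w$tensor == nm, , drop = FALSE]
    sh <- shapes[[nm]]
    if (nrow(ww) != prod(sh))
      stop("checkpoint tensor '", nm, "' has wrong size")
    m <- matrix(NA_real_, sh[1L], sh[2L])
    m[cbind(ww$row, ww$col)] <- ww$value
    params[[nm]] <- switch(nm,
      W_P = , E_A = m,
      b = m[1L, 1L],
      as.vector(m))
  }
  rownames(params$E_A) <- header$vocabulary
  structure(list(params = params, vocabulary = header$vocabulary,
                 schema = schema, config = cfg, loss = numeric(0),
                 fitted.values = NULL, residuals = NULL, y = NULL,
                 n_examples = header$n_examples, call = NULL),
            class = "adrnet")
}
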
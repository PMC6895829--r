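# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Split a semicolon-joined prescription string into a character vector of
# drug names; "" or NA -> character(0).
parse_drugs <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

join_drugs <- function(drugs) paste(drugs, collapse = ";")

# n x |vocabulary| 0/1 incidence matrix from a character vector of
# semicolon-joined prescriptions.
drug_incidence <- function(drugs, vocabulary) {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 1L)
  n <- length(drugs)
  M <- matrix(0, n, length(vocabulary),
              dimnames = list(NULL, vocabulary))
  for (i in seq_len(n)) {
    di <- parse_drugs(drugs[i])
    if (length(di) == 0L)
      stop("empty prescription in row ", i,
           " (every prescription must contain at least one drug)")
    unknown <- setdiff(di, vocabulary)
    if (length(unknown))
      stop("unknown drug name(s): ", paste(unknown, collapse = ", "))
    M[i, di] <- 1
  }
  M
}

# Truncated normal sampler by inverse-CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

# round-half-up to an integer (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
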
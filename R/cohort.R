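#' Default covariate block schema
#'
#' The post-selection covariate layout used throughout the package: a
#' 127-dimensional demographic block (demographics bypass data-driven
#' selection) and three 20-dimensional selected blocks of neuroimaging
#' biomarkers, genetic variants and DNA-methylation levels.
#'
#' @return Named integer vector of block widths.
#' @export
default_schema <- function() {
  c(demographic = 127L, biomarkers = 20L, variants = 20L, methylation = 20L)
}

# Internal: check a feature-block list against a schema; returns the schema.
check_features <- function(features, schema = NULL) {
  stopifnot(is.list(features), length(features) >= 1L)
  if (is.null(schema))
    schema <- vapply(features, ncol, integer(1))
  if (!identical(names(features), names(schema)))
    stop("feature blocks must be named ", paste(names(schema), collapse = "/"))
  ids <- rownames(features[[1L]])
  for (b in names(features)) {
    m <- features[[b]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("block '", b, "' must be a numeric matrix")
    if (ncol(m) != schema[[b]])
      stop("block '", b, "' has ", ncol(m), " columns; schema expects ",
           schema[[b]])
    if (!identical(rownames(m), ids))
      stop("all blocks must share identical patient_id rownames")
  }
  invisible(schema)
}

#' Random-donor imputation of missing covariates
#'
#' Each missing entry (an `NA`) is replaced by the value at the same feature
#' index from a uniformly sampled other patient whose entry is observed,
#' independently per entry. Non-missing values are never altered. The original
#' missingness pattern is retained on each block as the logical
#' `attr(block, "missing")` matrix.
#'
#' @param features Named list of numeric patient-by-feature matrices (one per
#'   covariate block, shared `patient_id` rownames); `NA` marks missing.
#' @param seed Integer seed making the donor draws reproducible.
#' @return The feature-block list with every `NA` imputed.
#' @export
impute_missing <- function(features, seed = NULL) {
  check_features(features)
  with_seed(seed, {
    for (b in names(features)) {
      m <- features[[b]]
      mask <- is.na(m)
      for (j in seq_len(ncol(m))) {
        miss <- which(mask[, j])
        if (!length(miss)) next
        donors <- which(!mask[, j])
        if (!length(donors))
          stop("feature index ", j, " of block '", b,
               "' is missing for all patients; no donor available")
        picks <- donors[sample.int(length(donors), length(miss),
                                   replace = TRUE)]
        m[miss, j] <- m[picks, j]
      }
      attr(m, "missing") <- mask
      features[[b]] <- m
    }
    features
  })
}

# Internal: validate a visit table and return it ordered by patient/visit.
check_visits <- function(visits) {
  need <- c("patient_id", "visit_index", "weeks_since_prev", "hamd", "drugs")
  if (!all(need %in% names(visits)))
    stop("visit table must have columns: ", paste(need, collapse = ", "))
  if (any(visits$hamd < 0, na.rm = TRUE))
    stop("HAM-D scores must be non-negative")
  visits <- visits[order(visits$patient_id, visits$visit_index), ,
                   drop = FALSE]
  for (pid in unique(visits$patient_id)) {
    vi <- visits$visit_index[visits$patient_id == pid]
    if (anyDuplicated(vi))
      stop("duplicated visit_index for patient ", pid,
           " (simultaneous visits are rejected)")
    if (any(diff(vi) <= 0))
      stop("visit_index not strictly increasing for patient ", pid)
  }
  visits
}

#' Build one-step training examples from visit records
#'
#' Forms one training example per pair of consecutive visits of a patient:
#' predictors are the patient state and the prescription at the earlier visit
#' plus the interval to the later visit; the target is the later visit's HAM-D
#' score. Patients with a single record contribute no examples.
#'
#' @param visits Data frame with columns `patient_id`, `visit_index` (strictly
#'   increasing within patient), `weeks_since_prev` (interval in weeks from
#'   the previous visit, `NA` for the first), `hamd`, and `drugs`
#'   (semicolon-joined drug names prescribed at that visit).
#' @return Data frame of examples with columns `patient_id`, `from_visit`,
#'   `hamd_now`, `interval`, `drugs`, `hamd_next`.
#' @export
build_pairs <- function(visits) {
  visits <- check_visits(visits)
  out <- list()
  for (pid in unique(visits$patient_id)) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    n <- nrow(v)
    if (n < 2L) next
    iv <- v$weeks_since_prev[-1L]
    if (any(is.na(iv)) || any(iv <= 0))
      stop("weeks_since_prev must be positive for every non-initial visit ",
           "(patient ", pid, ")")
    if (any(!nzchar(v$drugs[-n]) | is.na(v$drugs[-n])))
      stop("patient ", pid, ": empty prescription at a visit used as the ",
           "'from' side of a training pair")
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid,
      from_visit = v$visit_index[-n],
      hamd_now   = v$hamd[-n],
      interval   = iv,
      drugs      = v$drugs[-n],
      hamd_next  = v$hamd[-1L],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(patient_id = character(0), from_visit = integer(0),
                      hamd_now = numeric(0), interval = numeric(0),
                      drugs = character(0), hamd_next = numeric(0)))
  ex <- do.call(rbind, out)
  rownames(ex) <- NULL
  ex
}

#' Clinical remission label for one visit sequence
#'
#' Remission is operationalised as a last-visit HAM-D score at most half the
#' initial-visit score: the label is 1 when `last / first <= 0.5` (boundary
#' inclusive) and 0 otherwise. A zero initial score makes the ratio undefined
#' and is an error.
#'
#' @param hamd Numeric vector of HAM-D scores in visit order (length >= 2).
#' @return 0 or 1.
#' @export
remission_label <- function(hamd) {
  stopifnot(is.numeric(hamd))
  if (length(hamd) < 2L)
    stop("at least two visit scores are required")
  if (hamd[1L] <= 0)
    stop("initial HAM-D score must be positive (remission ratio undefined)")
  as.integer(hamd[length(hamd)] / hamd[1L] <= 0.5)
}

#' Per-patient remission cases
#'
#' Reduces a visit table to one row per patient with at least two visits,
#' carrying the first and last observed HAM-D scores and the remission label
#' from [remission_label()].
#'
#' @inheritParams build_pairs
#' @return Data frame with columns `patient_id`, `n_visits`, `hamd_first`,
#'   `hamd_last`, `label`.
#' @export
remission_cases <- function(visits) {
  visits <- check_visits(visits)
  pats <- unique(visits$patient_id)
  rows <- lapply(pats, function(pid) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    if (nrow(v) < 2L) return(NULL)
    data.frame(patient_id = pid, n_visits = nrow(v),
               hamd_first = v$hamd[1L], hamd_last = v$hamd[nrow(v)],
               label = remission_label(v$hamd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), n_visits = integer(0),
                      hamd_first = numeric(0), hamd_last = numeric(0),
                      label = integer(0))
  rownames(out) <- NULL
  out
}

#' Random train/test split
#'
#' Partitions examples into disjoint, exhaustive train and test sets. The test
#' size is `round(N * test_fraction)` with halves rounded up.
#'
#' @param examples Data frame of examples (any row-indexed data).
#' @param test_fraction Fraction held out, strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(examples, test_fraction = 0.1, seed = NULL) {
  n <- nrow(examples)
  if (is.null(n) || n < 2L) stop("need at least two examples to split")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)")
  n_test <- round_half_up(n * test_fraction)
  idx <- with_seed(seed, sample.int(n))
  test_idx <- sort(idx[seq_len(n_test)])
  list(train = examples[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test  = examples[test_idx, , drop = FALSE])
}

#' Read and write cohort tables
#'
#' A cohort on disk is three plain-text files: `visits.csv` (one row per
#' visit: `patient_id, visit_index, weeks_since_prev, hamd, drugs` with drugs
#' semicolon-joined), `features.csv` in long form (`patient_id, block, index,
#' value, missing`), and a one-column drug vocabulary file whose line order
#' fixes one-hot and embedding-row indices.
#'
#' @param visits_file,features_file,vocab_file File paths.
#' @return `read_cohort()` returns a list with `visits` (data frame),
#'   `features` (named list of patient-by-feature matrices, `NA` = missing)
#'   and `vocabulary` (character vector).
#' @export
read_cohort <- function(visits_file, features_file, vocab_file) {
  for (f in c(visits_file, features_file, vocab_file))
    if (!file.exists(f)) stop("file not found: ", f)
  visits <- read.csv(visits_file, stringsAsFactors = FALSE,
                     colClasses = c(drugs = "character"))
  visits <- check_visits(visits)
  long <- read.csv(features_file, stringsAsFactors = FALSE)
  need <- c("patient_id", "block", "index", "value", "missing")
  if (!all(need %in% names(long)))
    stop("features file must have columns: ", paste(need, collapse = ", "))
  ids <- unique(long$patient_id)
  blocks <- unique(long$block)
  features <- lapply(blocks, function(b) {
    lb <- long[long$block == b, , drop = FALSE]
    p <- max(lb$index)
    m <- matrix(NA_real_, length(ids), p, dimnames = list(ids, NULL))
    m[cbind(match(lb$patient_id, ids), lb$index)] <-
      ifelse(lb$missing > 0, NA_real_, lb$value)
    m
  })
  names(features) <- blocks
  vocabulary <- read_vocabulary(vocab_file)
  list(visits = visits, features = features, vocabulary = vocabulary)
}

#' @rdname read_cohort
#' @param cohort List with `visits`, `features`, `vocabulary` as returned by
#'   [read_cohort()] or [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `write_cohort()` invisibly returns the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vf <- file.path(dir, "visits.csv")
  ff <- file.path(dir, "features.csv")
  af <- file.path(dir, "vocabulary.txt")
  write.csv(cohort$visits, vf, row.names = FALSE)
  long <- do.call(rbind, lapply(names(cohort$features), function(b) {
    m <- cohort$features[[b]]
    data.frame(patient_id = rep(rownames(m), ncol(m)),
               block = b,
               index = rep(seq_len(ncol(m)), each = nrow(m)),
               value = as.vector(ifelse(is.na(m), 0, m)),
               missing = as.integer(as.vector(is.na(m))),
               stringsAsFactors = FALSE)
  }))
  write.csv(long, ff, row.names = FALSE)
  writeLines(cohort$vocabulary, af)
  invisible(c(vf, ff, af))
}

#' @rdname read_cohort
#' @export
read_vocabulary <- function(vocab_file) {
  if (!file.exists(vocab_file)) stop("file not found: ", vocab_file)
  v <- trimws(readLines(vocab_file))
  v <- v[nzchar(v)]
  if (anyDuplicated(v)) stop("drug vocabulary contains duplicate names")
  v
}
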
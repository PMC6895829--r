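# Use-case engines: exhaustive prescription ranking and patient-similarity
# retrieval from the learned representation vectors.

#' Enumerate prescription candidates
#'
#' All single drugs plus, when `max_combo_size = 2`, all unordered pairs of
#' distinct drugs: `n + n(n-1)/2` candidates (14 drugs give 14 + 91 = 105).
#'
#' @param vocabulary Non-empty character vector of drug names.
#' @param max_combo_size 1 or 2; larger combinations are out of scope.
#' @return List of character vectors (each a candidate drug set).
#' @export
enumerate_candidates <- function(vocabulary, max_combo_size = 2L) {
  if (length(vocabulary) == 0L) stop("vocabulary is empty")
  if (!max_combo_size %in% 1:2)
    stop("max_combo_size must be 1 or 2")
  singles <- lapply(vocabulary, identity)
  if (max_combo_size == 1L || length(vocabulary) < 2L) return(singles)
  pairs <- utils::combn(vocabulary, 2L, simplify = FALSE)
  c(singles, pairs)
}

#' Rank prescription candidates for one patient state
#'
#' Predicts the next-visit HAM-D score for every candidate at the given
#' interval and ranks candidates ascending by predicted score (lower is
#' better, rank 1 = most effective); exact ties are broken lexicographically
#' by the semicolon-joined drug names.
#'
#' @param object A fitted `"adrnet"` model.
#' @param features Imputed covariate blocks containing the patient.
#' @param patient_id The patient to rank for.
#' @param hamd_now Current HAM-D score.
#' @param interval Weeks until the next visit.
#' @param candidates List of candidate drug sets; default
#'   [enumerate_candidates()] over the model vocabulary.
#' @return Data frame with columns `prescription`, `predicted_hamd`, `rank`,
#'   sorted by rank.
#' @export
rank_prescriptions <- function(object, features, patient_id, hamd_now,
                               interval,
                               candidates =
                                 enumerate_candidates(object$vocabulary)) {
  stopifnot(inherits(object, "adrnet"), length(candidates) >= 1L)
  rx <- vapply(candidates, function(d) join_drugs(sort(d)), character(1))
  ex <- data.frame(patient_id = patient_id, hamd_now = hamd_now,
                   interval = interval, drugs = rx,
                   stringsAsFactors = FALSE)
  pred <- predict(object, ex, features)
  ord <- order(pred, rx)
  out <- data.frame(prescription = rx[ord], predicted_hamd = pred[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a prescription policy over a patient's visit sequence
#'
#' Rolls the one-step predictor along the patient's recorded visit schedule,
#' feeding predictions forward, with the prescription at each step chosen by
#' the policy: `"actual"` uses the recorded prescription (the same trajectory
#' the remission rollout traverses), `"best"` re-ranks all candidates at each
#' visit against the current predicted state and takes the top candidate.
#'
#' @param object A fitted `"adrnet"` model.
#' @param visits Visit table of a single patient (>= 2 visits).
#' @param features Imputed covariate blocks.
#' @param policy `"actual"` or `"best"`.
#' @return Data frame with one row per visit: `visit_index`, `week`,
#'   `hamd_pred` (first row is the observed baseline), `prescription`.
#' @export
simulate_policy <- function(object, visits, features,
                            policy = c("actual", "best")) {
  policy <- match.arg(policy)
  visits <- check_visits(visits)
  if (length(unique(visits$patient_id)) != 1L)
    stop("simulate_policy expects the visits of a single patient")
  nv <- nrow(visits)
  if (nv < 2L) stop("at least two visits are required")
  pid <- visits$patient_id[1L]
  weeks <- cumsum(c(0, visits$weeks_since_prev[-1L]))
  h <- visits$hamd[1L]
  traj <- data.frame(visit_index = visits$visit_index, week = weeks,
                     hamd_pred = NA_real_, prescription = NA_character_,
                     stringsAsFactors = FALSE)
  traj$hamd_pred[1L] <- h
  for (i in seq_len(nv - 1L)) {
    dt <- visits$weeks_since_prev[i + 1L]
    rx <- if (policy == "actual") visits$drugs[i]
    else rank_prescriptions(object, features, pid, h, dt)$prescription[1L]
    ex <- data.frame(patient_id = pid, hamd_now = h, interval = dt,
                     drugs = rx, stringsAsFactors = FALSE)
    h <- predict(object, ex, features)
    traj$hamd_pred[i + 1L] <- h
    traj$prescription[i] <- rx
  }
  traj
}

#' Patient representation embeddings
#'
#' Computes each patient's representation vector (the patient-layer
#' activation, dropout off) at their most recent visit state: covariates plus
#' the last observed HAM-D score, with the interval term set to the patient's
#' most recent inter-visit interval (or `interval` if given).
#'
#' @param object A fitted `"adrnet"` model.
#' @param visits Visit table.
#' @param features Imputed covariate blocks.
#' @param interval Interval (weeks) entering the state; `NULL` uses each
#'   patient's most recent inter-visit interval, falling back to 4 for
#'   single-visit patients.
#' @return Numeric matrix, one row per patient (rownames = `patient_id`),
#'   `d` columns.
#' @export
embed_patients <- function(object, visits, features, interval = NULL) {
  stopifnot(inherits(object, "adrnet"))
  visits <- check_visits(visits)
  pats <- unique(visits$patient_id)
  state <- do.call(rbind, lapply(pats, function(pid) {
    v <- visits[visits$patient_id == pid, , drop = FALSE]
    last <- nrow(v)
    iv <- interval %||%
      (if (last >= 2L) v$weeks_since_prev[last] else 4)
    data.frame(patient_id = pid, hamd_now = v$hamd[last], interval = iv,
               stringsAsFactors = FALSE)
  }))
  X <- build_design(features, state)
  V <- patient_repr(X, object$params, object$config$nonlinearity)
  rownames(V) <- pats
  V
}

cosine_sim <- function(q, M) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("zero-norm query vector: cosine similarity undefined")
  Mn <- sqrt(rowSums(M^2))
  as.vector(M %*% q) / (Mn * qn)
}

#' Retrieve the most similar patients
#'
#' Ranks an embedding index by cosine similarity to a query vector,
#' descending, with ties broken by patient id. Index members with a zero-norm
#' vector are dropped with a warning (their similarity is undefined).
#'
#' @param query Numeric query vector, or a patient id present in `index`.
#' @param index Embedding matrix from [embed_patients()].
#' @param k Number of neighbours (`k <= nrow(index)`).
#' @return Data frame `patient_id`, `similarity`, ordered by rank.
#' @export
nearest_patients <- function(query, index, k = 5L) {
  if (is.character(query)) {
    if (!query %in% rownames(index)) stop("unknown patient id: ", query)
    query <- index[query, ]
  }
  if (k > nrow(index)) stop("k exceeds the index size")
  sims <- cosine_sim(query, index)
  ids <- rownames(index)
  bad <- !is.finite(sims)
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-norm index member(s)")
    sims <- sims[!bad]; ids <- ids[!bad]
    if (k > length(sims)) k <- length(sims)
  }
  ord <- order(-sims, ids)[seq_len(k)]
  data.frame(patient_id = ids[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}

#' Cluster patients in representation space
#'
#' Plain k-means over the embedding matrix.
#'
#' @param index Embedding matrix from [embed_patients()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return Named integer vector of cluster ids.
#' @export
cluster_patients <- function(index, k = 2L, seed = 1L) {
  with_seed(seed, {
    cl <- kmeans(index, centers = k, nstart = 10L)
    structure(cl$cluster, names = rownames(index))
  })
}
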
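# Small in-code fixtures shared across test files.

tiny_schema <- function() {
  c(demographic = 4L, biomarkers = 2L, variants = 2L, methylation = 2L)
}

# A deterministic three-patient visit table (weeks 0/1/4/8 pattern).
tiny_visits <- function() {
  data.frame(
    patient_id = rep(c("A", "B", "C"), times = c(4L, 2L, 1L)),
    visit_index = c(1:4, 1:2, 1L),
    weeks_since_prev = c(NA, 1, 3, 4, NA, 4, NA),
    hamd = c(20, 18, 12, 9, 24, 13, 15),
    drugs = c("FLUOXETINE", "FLUOXETINE", "FLUOXETINE;MIRTAZAPINE",
              "SERTRALINE", "SERTRALINE", "SERTRALINE", "FLUOXETINE"),
    stringsAsFactors = FALSE)
}

tiny_vocab <- function() c("FLUOXETINE", "MIRTAZAPINE", "SERTRALINE")

# Feature blocks for the three patients above, no missingness.
tiny_features <- function(schema = tiny_schema(), ids = c("A", "B", "C"),
                          seed = 5L) {
  set.seed(seed)
  feats <- lapply(schema, function(p) {
    m <- matrix(rnorm(length(ids) * p), length(ids), p)
    rownames(m) <- ids
    m
  })
  feats
}

# A hand-sized planted model + sampled examples used by several model tests.
tiny_planted <- function(n = 60L, noise_sd = 0, seed = 2L) {
  pm <- planted_model(schema = tiny_schema(), vocabulary = tiny_vocab(),
                      d = 3L, d_prime = 2L, seed = seed)
  dat <- generate_from_planted(pm, n = n, noise_sd = noise_sd, seed = seed)
  dat
}
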
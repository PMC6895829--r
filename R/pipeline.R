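# End-to-end orchestration: simulate (or load) -> impute -> select -> train
# -> evaluate -> rank, with a manifest recording seed and config hash so a
# run can be reproduced exactly.

#' Run the full pipeline
#'
#' Executes simulate/load, imputation, feature selection, train/test split,
#' network training, two-task evaluation (plus optional generic-regressor
#' baselines), and an example prescription ranking; writes every artifact
#' under `out_dir` together with a manifest (seed, config hash, package
#' version). Artifact filenames carry the seed and the config hash. Any
#' stage failure aborts with the stage name; artifacts from completed stages
#' are retained.
#'
#' @param config Named list; recognised entries: `sim` (arguments for
#'   [sim_config()], used when no cohort files are given), `visits_file` /
#'   `features_file` / `vocab_file` (load an existing cohort instead),
#'   `select` (arguments for [select_block()] via [select_features()]),
#'   `model` (hyperparameters for [adrnet()]), `test_fraction` (default 0.1),
#'   `baselines` (character vector of suite members, `NULL` for none),
#'   `rank_patient` (patient id to rank for; default the first test patient).
#' @param out_dir Output directory (created).
#' @param seed Global integer seed; recorded in the manifest and all
#'   artifact names.
#' @return Invisibly, a list with the fitted model, evaluation report,
#'   selection results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  hash <- substr(unname(tools::md5sum(cfg_file)), 1L, 8L)
  tag <- sprintf("seed%d_%s", seed, hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$visits_file)) {
      for (f in c(config$visits_file, config$features_file,
                  config$vocab_file))
        if (!file.exists(f)) stop("file not found: ", f)
      read_cohort(config$visits_file, config$features_file,
                  config$vocab_file)
    } else {
      sc <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
      sim <- generate_cohort(sc)
      write_cohort(sim, file.path(out_dir, paste0("cohort_", tag)))
      sim
    }
  })

  sel <- stage("select", {
    do.call(select_features,
            c(list(cohort = cohort, seed = seed), config$select %||% list()))
  })
  feats <- sel$features
  if (length(sel$selection)) {
    sel_json <- lapply(sel$selection, function(s)
      list(block = s$block, coefficients = unname(s$coefficients),
           selected = s$selected, seed = seed, config_hash = hash))
    jsonlite::write_json(sel_json,
                         file.path(out_dir,
                                   paste0("selection_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  split <- stage("split", {
    ex <- build_pairs(cohort$visits)
    split_dataset(ex, config$test_fraction %||% 0.1, seed = seed)
  })

  fit <- stage("train", {
    do.call(adrnet, c(list(examples = split$train, features = feats,
                           vocabulary = cohort$vocabulary, seed = seed),
                      config$model %||% list()))
  })
  save_adrnet(fit, file.path(out_dir, paste0("checkpoint_", tag)))

  report <- stage("evaluate", {
    test_patients <- unique(split$test$patient_id)
    ev <- evaluate_model(fit, split$test, feats,
                         visits = cohort$visits[
                           cohort$visits$patient_id %in% test_patients, ,
                           drop = FALSE])
    out <- list(seed = seed, config_hash = hash,
                task1 = list(rmse = ev$rmse, r_squared = ev$r_squared,
                             n = ev$n_examples),
                task2 = c(as.list(ev$classification[
                  c("sensitivity", "specificity", "precision", "f1",
                    "accuracy")]), n = ev$n_cases))
    if (!is.null(config$baselines)) {
      bl <- run_baselines(split$train, split$test, feats,
                          cohort$vocabulary,
                          suite = baseline_suite(config$baselines),
                          seed = seed)
      out$baselines <- bl
    }
    jsonlite::write_json(out, file.path(out_dir,
                                        paste0("eval_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })

  ranking <- stage("rank", {
    pid <- config$rank_patient %||% split$test$patient_id[1L]
    st <- split$test[split$test$patient_id == pid, , drop = FALSE]
    if (nrow(st) == 0L) st <- split$train[split$train$patient_id == pid, ,
                                          drop = FALSE]
    if (nrow(st) == 0L) stop("unknown rank_patient: ", pid)
    rk <- rank_prescriptions(fit, feats, pid, st$hamd_now[1L],
                             st$interval[1L])
    write.csv(rk, file.path(out_dir, paste0("ranking_", tag, ".csv")),
              row.names = FALSE)
    rk
  })

  manifest <- list(seed = seed, config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("adrnet")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   artifacts = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", tag, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fit = fit, report = report, selection = sel$selection,
                 ranking = ranking, manifest = manifest))
}
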
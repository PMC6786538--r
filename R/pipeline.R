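#' Assemble a full pipeline configuration
#'
#' Bundles input locations, the experiment design, EM settings, the
#' selection mode and the output directory into one serializable object. The
#' effective configuration is always written next to a run's outputs.
#'
#' @param matrix_file Expression matrix path (TSV/CSV), or `NULL` when
#'   `tensors` are passed to [run_pipeline()] directly.
#' @param column_map Column-map path or data frame (see
#'   [load_expression()]).
#' @param design An [experiment_design()].
#' @param em An [em_config()].
#' @param selection_mode `"whole-path"` or `"per-step"` (see
#'   [select_relevant()]).
#' @param shuffle_seed Seed of the feature shuffle applied before fitting.
#' @param outdir Output directory, or `NULL` to skip writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix_file = NULL, column_map = NULL, design,
                       em = em_config(),
                       selection_mode = c("whole-path", "per-step"),
                       shuffle_seed = 1729L, outdir = NULL) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(inherits(design, "experiment_design"), inherits(em, "em_config"))
  structure(list(matrix_file = matrix_file, column_map = column_map,
                 design = design, em = em, selection_mode = selection_mode,
                 shuffle_seed = as.integer(shuffle_seed), outdir = outdir),
            class = "run_config")
}

#' Run the full feature-selection pipeline
#'
#' Executes load -> difference -> (summarize) -> shuffle -> EM fit ->
#' per-feature per-condition Viterbi decoding -> cross-condition selection
#' -> scoring -> ranking. When `config$outdir` is set, writes `ranked.tsv`,
#' `selection.tsv`, `model.json`, `run_config.json` and `log.txt`.
#'
#' @param config A [run_config()].
#' @param tensors Optional named list of [condition_tensor()] objects (e.g.
#'   from [simulate_dataset()]); when given, `matrix_file`/`column_map` are
#'   ignored.
#' @return A list with `fit` (the `hmm_fit`), `selection` (per-feature
#'   selection table), `ranked` (ranked table of relevant features) and
#'   `paths` (per-condition decoded path matrices).
#' @export
run_pipeline <- function(config, tensors = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (is.null(tensors)) {
    if (is.null(config$matrix_file))
      stop("stage load: no matrix_file in config and no tensors supplied")
    tensors <- load_expression(config$matrix_file, design,
                               config$column_map)
  } else if (design$replicate_summary != "none") {
    tensors <- lapply(tensors, summarize_replicates,
                      method = design$replicate_summary)
  }
  G <- length(tensors[[1L]]$feature_ids)
  say("load: ", G, " features, ", length(tensors), " conditions")

  deltas <- lapply(tensors, delta_transform)
  say("delta: ", dim(deltas[[1L]]$deltas)[3L], " time steps per sequence")

  shuffled <- shuffle_features(deltas, seed = config$shuffle_seed)
  fit <- em_fit(shuffled, config$em)
  say(sprintf("fit: %d sequences, %d iterations (%s), log-likelihood %.6g",
              fit$n_sequences, fit$iterations,
              if (fit$converged) "converged" else "max_iter",
              utils::tail(fit$log_likelihood_trace, 1L)))

  paths <- lapply(deltas, function(d) decode_condition(fit$parameters, d))
  selection <- select_relevant(paths, design, mode = config$selection_mode)
  say("select: ", sum(selection$relevant), " of ", G, " features relevant")

  keep <- selection$relevant
  rel_ids <- selection$feature_id[keep]
  scores <- score_all_features(
    lapply(paths, function(p) p[keep, , drop = FALSE]),
    lapply(deltas, function(d)
      delta_tensor(d$condition, d$deltas[keep, , , drop = FALSE], rel_ids)),
    lapply(tensors, function(v)
      condition_tensor(v$condition, v$values[keep, , , drop = FALSE],
                       rel_ids)))
  ranked <- rank_features(scores)
  path_cols <- selection[keep, grep("^path_", names(selection)),
                         drop = FALSE]
  ranked <- merge(ranked, cbind(feature_id = rel_ids, path_cols),
                  by = "feature_id", sort = FALSE)
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  rownames(ranked) <- NULL
  say("rank: ", nrow(ranked), " features ranked")

  result <- list(fit = fit, selection = selection, ranked = ranked,
                 paths = paths)

  if (!is.null(config$outdir)) {
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) unlink(file.path(outdir,
                                      c("ranked.tsv", "selection.tsv",
                                        "model.json", "run_config.json",
                                        "log.txt"))), add = TRUE)
    utils::write.table(format_numeric_df(ranked),
                       file.path(outdir, "ranked.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(selection, file.path(outdir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_model_json(fit, file.path(outdir, "model.json"))
    jsonlite::write_json(serialize_run_config(config),
                         file.path(outdir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(outdir, "log.txt"))
    ok <- TRUE
  }
  attr(result, "log") <- log_lines
  result
}

serialize_run_config <- function(config) {
  list(matrix_file = config$matrix_file,
       column_map = if (is.character(config$column_map))
         config$column_map else "<in-memory>",
       design = unclass(config$design),
       em = unclass(config$em),
       selection_mode = config$selection_mode,
       shuffle_seed = config$shuffle_seed,
       outdir = config$outdir)
}
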
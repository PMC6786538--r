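#' Configuration of the synthetic time-course generator
#'
#' Defaults reproduce a typical two-condition RNA-seq time course at the
#' scale used to validate the method: 10,000 transcripts, 6 time points, 3
#' replicates, 10% of case-group features perturbed, per-state standard
#' deviations 1.0 ("change") and 0.2 ("no change"), and white measurement
#' noise on every replicate.
#'
#' @param n_features Number of transcripts (default 10000).
#' @param n_timepoints Number of time points T (default 6).
#' @param n_replicates Replicates per condition (default 3).
#' @param frac_perturbed Fraction of case-group features carrying at least
#'   one change (default 0.10).
#' @param sd_change Emission sd of state C (default 1.0).
#' @param sd_nochange Emission sd of state N (default 0.2).
#' @param replicate_noise_sd White measurement noise added independently to
#'   every replicate/time point (default 0.1).
#' @param transition Row-stochastic 2x2 matrix generating perturbed
#'   features' state paths; default has persistent states
#'   (`[[0.9, 0.1], [0.1, 0.9]]`).
#' @param initial Initial state distribution of the path generator; default
#'   `(0.9, 0.1)`, biased to the null state, consistent with changes being
#'   rare events.
#' @param baseline_range Range of the uniform baseline (log-expression-like)
#'   offsets; removed by differencing, kept for realism (default `c(2, 12)`).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_features = 10000L, n_timepoints = 6L,
                              n_replicates = 3L, frac_perturbed = 0.10,
                              sd_change = 1.0, sd_nochange = 0.2,
                              replicate_noise_sd = 0.1,
                              transition = matrix(c(0.9, 0.1, 0.1, 0.9),
                                                  2L, byrow = TRUE),
                              initial = c(0.9, 0.1),
                              baseline_range = c(2, 12), seed = 1L) {
  if (frac_perturbed < 0 || frac_perturbed > 1)
    stop("configuration error: frac_perturbed must lie in [0, 1]")
  if (!(sd_change > sd_nochange && sd_nochange > 0))
    stop("configuration error: need sd_change > sd_nochange > 0")
  if (any(abs(rowSums(transition) - 1) > 1e-10) || any(transition < 0))
    stop("configuration error: transition must be row-stochastic")
  if (abs(sum(initial) - 1) > 1e-10 || any(initial < 0))
    stop("configuration error: initial must be a probability vector")
  stopifnot(n_features >= 1L, n_timepoints >= 2L, n_replicates >= 1L)
  structure(list(n_features = as.integer(n_features),
                 n_timepoints = as.integer(n_timepoints),
                 n_replicates = as.integer(n_replicates),
                 frac_perturbed = frac_perturbed, sd_change = sd_change,
                 sd_nochange = sd_nochange,
                 replicate_noise_sd = replicate_noise_sd,
                 transition = transition, initial = initial,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "simulation_config")
}

# sample n state paths of given length from the two-state chain;
# returns integer matrix (1 = N, 2 = C)
sample_state_paths <- function(n, len, initial, transition) {
  paths <- matrix(1L, n, len)
  paths[, 1L] <- 1L + (stats::runif(n) < initial[2L])
  if (len > 1L) for (t in 2:len) {
    p_c <- transition[paths[, t - 1L], 2L]
    paths[, t] <- 1L + (stats::runif(n) < p_c)
  }
  paths
}

#' Simulate a two-condition time-course expression dataset
#'
#' Control-group features never change: their underlying state path is
#' all-N. In the case group, a `frac_perturbed` fraction of features gets a
#' state path sampled from the configured Markov chain, rejected until it
#' contains at least one C; the remaining case features are all-N too. At
#' each time step every replicate's expression change is drawn independently
#' from the state's Gaussian (sd `sd_change` or `sd_nochange`, mean 0) --
#' one draw per replicate, matching the model's R-dimensional emission.
#' Changes are cumulatively summed from a per-feature uniform baseline, and
#' white noise (`replicate_noise_sd`) is added to every measurement.
#'
#' @param config A [simulation_config()].
#' @return A list with `tensors` (named list of [condition_tensor()]:
#'   `control`, `case`), `truth` (data frame: `feature_id`, `has_change`,
#'   `path_control`, `path_case` -- the generating paths as "N"/"C"
#'   strings), `design` (the matching [experiment_design()]) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  G <- config$n_features; Tn <- config$n_timepoints
  R <- config$n_replicates; Tm <- Tn - 1L
  ids <- sprintf("gene_%05d", seq_len(G))

  n_pert <- round(G * config$frac_perturbed)
  perturbed <- seq_len(G) <= n_pert   # feature order is arbitrary by design

  # case-group paths: all-N except perturbed features, which draw from the
  # chain until the path carries at least one change
  case_paths <- matrix(1L, G, Tm)
  if (n_pert > 0L) {
    todo <- seq_len(n_pert)
    while (length(todo)) {
      cand <- sample_state_paths(length(todo), Tm, config$initial,
                                 config$transition)
      ok <- rowSums(cand == 2L) > 0
      case_paths[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
  }
  ctrl_paths <- matrix(1L, G, Tm)

  sds <- c(config$sd_nochange, config$sd_change)
  build_tensor <- function(paths, cond) {
    # per-replicate deltas drawn from the state Gaussian
    del <- array(stats::rnorm(G * R * Tm), c(G, R, Tm))
    for (t in seq_len(Tm)) del[, , t] <- del[, , t] * sds[paths[, t]]
    base <- stats::runif(G, config$baseline_range[1L],
                         config$baseline_range[2L])
    vals <- array(0, c(G, R, Tn))
    vals[, , 1L] <- base
    for (t in seq_len(Tm)) vals[, , t + 1L] <- vals[, , t] + del[, , t]
    vals <- vals + array(stats::rnorm(G * R * Tn, 0,
                                      config$replicate_noise_sd),
                         c(G, R, Tn))
    condition_tensor(cond, vals, ids)
  }
  tensors <- list(control = build_tensor(ctrl_paths, "control"),
                  case = build_tensor(case_paths, "case"))

  truth <- data.frame(
    feature_id = ids,
    has_change = perturbed,
    path_control = apply(matrix(c("N", "C")[ctrl_paths], G, Tm), 1L,
                         paste, collapse = ""),
    path_case = apply(matrix(c("N", "C")[case_paths], G, Tm), 1L,
                      paste, collapse = ""),
    stringsAsFactors = FALSE)

  design <- experiment_design(time_points = seq_len(Tn) - 1,
                              conditions = c("control", "case"),
                              control = "control", replicates = R)
  list(tensors = tensors, truth = truth, design = design, config = config)
}

#' Confusion-matrix evaluation of a selection against ground truth
#'
#' @param selected Character vector of selected feature ids (subset of the
#'   simulated ids).
#' @param truth Ground-truth data frame from [simulate_dataset()] (columns
#'   `feature_id`, `has_change`).
#' @return A list with `sensitivity` (TP / (TP + FN)), `precision`
#'   (TP / (TP + FP); `NA` when nothing was selected) and `counts` (named
#'   TP/FP/FN/TN vector).
#' @export
evaluate_detection <- function(selected, truth) {
  if (is.null(truth) || nrow(truth) == 0L)
    stop("invalid input: empty ground truth")
  extra <- setdiff(selected, truth$feature_id)
  if (length(extra))
    stop("selected ids absent from the ground truth: ",
         paste(utils::head(extra, 3L), collapse = ", "))
  sel <- truth$feature_id %in% selected
  pos <- truth$has_change
  tp <- sum(sel & pos); fp <- sum(sel & !pos)
  fn <- sum(!sel & pos); tn <- sum(!sel & !pos)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       counts = c(TP = tp, FP = fp, FN = fn, TN = tn))
}

#' Write a simulated dataset as loader-ready fixture files
#'
#' @param sim Result of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths of the written files: combined expression
#'   matrix TSV, column-map TSV and ground-truth TSV.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  matrix_file <- file.path(outdir, "expression.tsv")
  map_file <- file.path(outdir, "column_map.tsv")
  truth_file <- file.path(outdir, "ground_truth.tsv")
  write_expression(sim$tensors, sim$design, matrix_file, map_file)
  utils::write.table(sim$truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = matrix_file, column_map = map_file,
              truth = truth_file))
}
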
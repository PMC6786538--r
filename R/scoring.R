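#' Number of decoded changes for one feature
#'
#' Counts the `C` states over all conditions and time steps of one feature's
#' decoded paths. More decoded changes mean a stronger temporal signal.
#'
#' @param paths List (or single vector) of character state vectors over
#'   \{"N","C"\}, one per condition.
#' @return Nonnegative integer count.
#' @export
score_changes <- function(paths) {
  if (!is.list(paths)) paths <- list(paths)
  if (length(paths) == 0L || any(!lengths(paths)))
    stop("invalid input: empty path set")
  sum(vapply(paths, function(p) sum(p == "C"), 0L))
}

#' Magnitude of change for one feature
#'
#' Sums absolute delta values over all conditions, time steps and
#' replicates: a feature with a single but very large change still scores
#' high.
#'
#' @param deltas List (or single matrix) of numeric R x (T-1) delta blocks
#'   (replicates x steps), one per condition. Vectors are treated as R = 1.
#' @return Nonnegative real.
#' @export
score_magnitude <- function(deltas) {
  if (!is.list(deltas)) deltas <- list(deltas)
  dims <- lapply(deltas, function(d) dim(rbind(d)))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("alignment error: delta blocks disagree in shape across conditions")
  sum(vapply(deltas, function(d) sum(abs(d)), 0))
}

#' Replicate-consistency score for one feature
#'
#' Sums, over all conditions and all T time points, the absolute deviation
#' of replicates 2..R from replicate 1 on the raw (pre-difference)
#' expression values. Smaller values mean more consistent replicates and are
#' treated as better during ranking. With a single replicate the score is 0.
#'
#' @param values List (or single matrix) of numeric R x T expression blocks
#'   (replicates x time points), one per condition.
#' @return Nonnegative real.
#' @export
score_replicates <- function(values) {
  if (!is.list(values)) values <- list(values)
  Rs <- vapply(values, function(v) nrow(rbind(v)), 0L)
  if (length(unique(Rs)) != 1L)
    stop("alignment error: replicate counts differ across conditions")
  sum(vapply(values, function(v) {
    v <- rbind(v)
    if (nrow(v) < 2L) return(0)
    sum(abs(sweep(v[-1L, , drop = FALSE], 2L, v[1L, ])))
  }, 0))
}

#' Rank scored features into the final list
#'
#' Orders features by number of changes (descending), then magnitude of
#' change (descending), then replicate score (ascending: consistent
#' replicates win), then feature id; the 1-based position becomes the rank.
#' Per-score rank columns are added so users can re-rank by a single score.
#'
#' @param reports Data frame with columns `feature_id`, `n_changes`,
#'   `magnitude`, `replicate_score` (extra columns are carried through).
#' @param policy Currently only `"lexicographic"`.
#' @return The data frame reordered, with columns `rank`, `rank_n_changes`,
#'   `rank_magnitude`, `rank_replicates` added.
#' @export
rank_features <- function(reports, policy = "lexicographic") {
  policy <- match.arg(policy, "lexicographic")
  need <- c("feature_id", "n_changes", "magnitude", "replicate_score")
  if (!all(need %in% names(reports)))
    stop("reports must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(reports$feature_id))
    stop("validation error: duplicated feature_ids")
  if (nrow(reports) == 0L) {
    reports$rank <- integer(0)
    reports$rank_n_changes <- integer(0)
    reports$rank_magnitude <- integer(0)
    reports$rank_replicates <- integer(0)
    return(reports)
  }
  # radix: locale-independent id ordering, deterministic everywhere
  o <- order(-reports$n_changes, -reports$magnitude,
             reports$replicate_score, reports$feature_id, method = "radix")
  out <- reports[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rank_n_changes <- rank(-out$n_changes, ties.method = "min")
  out$rank_magnitude <- rank(-out$magnitude, ties.method = "min")
  out$rank_replicates <- rank(out$replicate_score, ties.method = "min")
  rownames(out) <- NULL
  out
}

# Vectorized scoring of all features at once (used by the pipeline).
# paths: named list of feature x (T-1) path matrices; deltas/values: named
# lists of delta_tensor / condition_tensor. Returns one row per feature.
score_all_features <- function(paths, deltas, values) {
  ids <- rownames(paths[[1L]])
  if (length(ids) == 0L)
    return(data.frame(feature_id = character(0), n_changes = integer(0),
                      magnitude = numeric(0), replicate_score = numeric(0),
                      stringsAsFactors = FALSE))
  n_changes <- Reduce(`+`, lapply(paths, function(p) rowSums(p == "C")))
  magnitude <- Reduce(`+`, lapply(deltas, function(d)
    apply(abs(d$deltas), 1L, sum)))
  replicate_score <- Reduce(`+`, lapply(values, function(v) {
    R <- dim(v$values)[2L]
    if (R < 2L) return(rep(0, length(ids)))
    dev <- abs(v$values[, -1L, , drop = FALSE] -
                 v$values[, rep(1L, R - 1L), , drop = FALSE])
    apply(dev, 1L, sum)
  }))
  data.frame(feature_id = ids, n_changes = as.integer(unname(n_changes)),
             magnitude = unname(magnitude),
             replicate_score = unname(replicate_score),
             stringsAsFactors = FALSE)
}
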
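#' Per-condition expression tensor
#'
#' A `condition_tensor` holds one condition's normalized expression values as
#' a 3-dimensional array: features x replicates x time points. This
#' rearrangement is what lets every feature act as its own observation
#' sequence when the model is fitted, so parameter estimation uses
#' features x conditions x replicates observations per time step instead of
#' a handful of samples.
#'
#' @param condition Condition name.
#' @param values Numeric array, features x replicates x time points.
#' @param feature_ids Character vector of feature identifiers (length =
#'   first dimension of `values`).
#' @return An object of class `condition_tensor`.
#' @export
condition_tensor <- function(condition, values, feature_ids) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array (features x replicates x time)")
  if (length(feature_ids) != dim(values)[1L])
    stop("feature_ids length (", length(feature_ids),
         ") does not match feature dimension (", dim(values)[1L], ")")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature identifiers")
  if (anyNA(values))
    stop("validation error: missing values in condition '", condition,
         "' (no imputation is performed)")
  if (!is.numeric(values))
    stop("values must be numeric")
  dimnames(values) <- list(feature_ids, NULL, NULL)
  structure(list(condition = condition, values = values,
                 feature_ids = as.character(feature_ids)),
            class = "condition_tensor")
}

#' @export
print.condition_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<condition_tensor> '%s': %d features x %d replicates x %d time points\n",
              x$condition, d[1], d[2], d[3]))
  invisible(x)
}

#' Per-condition tensor of consecutive-time expression differences
#'
#' @param condition Condition name.
#' @param deltas Numeric array, features x replicates x (T-1).
#' @param feature_ids Character vector of feature identifiers.
#' @return An object of class `delta_tensor`.
#' @seealso [delta_transform()]
#' @export
delta_tensor <- function(condition, deltas, feature_ids) {
  if (length(dim(deltas)) != 3L)
    stop("deltas must be a 3D array (features x replicates x time-1)")
  if (length(feature_ids) != dim(deltas)[1L])
    stop("feature_ids length does not match feature dimension")
  dimnames(deltas) <- list(feature_ids, NULL, NULL)
  structure(list(condition = condition, deltas = deltas,
                 feature_ids = as.character(feature_ids)),
            class = "delta_tensor")
}

#' @export
print.delta_tensor <- function(x, ...) {
  d <- dim(x$deltas)
  cat(sprintf("<delta_tensor> '%s': %d features x %d replicates x %d steps\n",
              x$condition, d[1], d[2], d[3]))
  invisible(x)
}

#' Difference consecutive time points of an expression tensor
#'
#' Transforms expression levels into expression *changes*: for every feature
#' and replicate, value at time t+1 minus value at time t. This removes each
#' feature's baseline offset, so two profiles with the same shape but
#' different starting levels become identical, and shortens the time axis
#' from T to T-1.
#'
#' @param tensor A [condition_tensor()].
#' @return A [delta_tensor()] with third dimension T-1.
#' @examples
#' ct <- condition_tensor("a", array(c(5, 7, 4), c(1, 1, 3)), "g1")
#' delta_transform(ct)$deltas[1, 1, ]  # 2, -3
#' @export
delta_transform <- function(tensor) {
  stopifnot(inherits(tensor, "condition_tensor"))
  Tn <- dim(tensor$values)[3L]
  if (Tn < 2L)
    stop("invalid design: delta transform needs at least 2 time points")
  d <- tensor$values[, , -1L, drop = FALSE] -
    tensor$values[, , -Tn, drop = FALSE]
  delta_tensor(tensor$condition, d, tensor$feature_ids)
}

#' Collapse replicates to a single profile per time point
#'
#' @param tensor A [condition_tensor()].
#' @param method `"mean"` or `"median"`, applied across replicates at each
#'   feature/time point.
#' @return A [condition_tensor()] with a single replicate.
#' @export
summarize_replicates <- function(tensor, method = c("mean", "median")) {
  stopifnot(inherits(tensor, "condition_tensor"))
  if (length(method) == 1L && !method %in% c("mean", "median"))
    stop("configuration error: unknown replicate summary method '",
         method, "'")
  method <- match.arg(method)
  if (dim(tensor$values)[2L] == 1L) return(tensor)
  summ <- apply(tensor$values, c(1L, 3L),
                if (method == "mean") mean else stats::median)
  out <- array(summ, dim = c(dim(tensor$values)[1L], 1L,
                             dim(tensor$values)[3L]))
  condition_tensor(tensor$condition, out, tensor$feature_ids)
}

#' Randomly permute the feature axis, identically across conditions
#'
#' The EM fit treats every feature as an observation sequence; shuffling
#' breaks any ordering structure in the input table (genes sorted by
#' chromosome, variance, ...) that could bias early iterations. The same
#' permutation is applied to every condition so that a feature's sequences
#' stay aligned, and the inverse permutation is attached so reports can be
#' produced in the original order.
#'
#' @param deltas A list of [delta_tensor()] objects sharing identical
#'   `feature_ids` order.
#' @param seed Integer seed; the permutation is reproducible from it.
#' @return The list with features permuted; attributes `permutation` and
#'   `inverse` hold the permutation and its inverse.
#' @export
shuffle_features <- function(deltas, seed = 1729L) {
  stopifnot(is.list(deltas), length(deltas) >= 1L)
  ids <- deltas[[1L]]$feature_ids
  for (d in deltas) {
    stopifnot(inherits(d, "delta_tensor"))
    if (!identical(d$feature_ids, ids))
      stop("alignment error: feature_ids differ across conditions")
  }
  G <- length(ids)
  perm <- local({
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    sample.int(G)
  })
  out <- lapply(deltas, function(d)
    delta_tensor(d$condition, d$deltas[perm, , , drop = FALSE],
                 d$feature_ids[perm]))
  names(out) <- names(deltas)
  attr(out, "permutation") <- perm
  attr(out, "inverse") <- order(perm)
  out
}

# save/restore .Random.seed so helper seeding does not clobber user RNG state
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
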
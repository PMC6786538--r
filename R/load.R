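#' Load a normalized expression matrix into per-condition tensors
#'
#' Reads a delimited expression table (rows = features, first column =
#' feature identifiers, remaining columns = samples) and rearranges it into
#' one features x replicates x time array per condition, following an
#' explicit sample-to-design assignment. The input is assumed already
#' normalized (typically log scale); no normalization, batch correction or
#' imputation is performed here.
#'
#' When replicate counts differ between conditions the emission
#' dimensionality of the downstream model would be ill-defined, so the
#' loader collapses replicates to their per-time-point mean (R = 1) and
#' warns.
#'
#' @param matrix_file Path to a TSV (or CSV, by `.csv` extension) expression
#'   matrix.
#' @param design An [experiment_design()].
#' @param column_map Sample assignment: a data frame (or path to a TSV) with
#'   columns `sample`, `condition`, `time`, `replicate`. Every
#'   (condition, time, replicate) cell of the design must map to exactly one
#'   sample column.
#' @return A named list of [condition_tensor()] objects, one per condition,
#'   in design order; features keep the table's row order in every tensor.
#' @export
load_expression <- function(matrix_file, design, column_map) {
  stopifnot(inherits(design, "experiment_design"))
  cmap <- read_column_map(column_map)
  tab <- read_matrix_table(matrix_file)
  mat <- tab$matrix
  feature_ids <- tab$feature_ids

  missing_samples <- setdiff(cmap$sample, colnames(mat))
  if (length(missing_samples))
    stop("design error: column_map samples absent from the matrix: ",
         paste(missing_samples, collapse = ", "))

  tp <- design$time_points
  tensors <- vector("list", length(design$conditions))
  names(tensors) <- design$conditions
  for (cond in design$conditions) {
    R <- design$replicates[[cond]]
    vals <- array(NA_real_, dim = c(nrow(mat), R, length(tp)))
    for (ti in seq_along(tp)) {
      for (r in seq_len(R)) {
        hit <- cmap$sample[cmap$condition == cond &
                             cmap$time == tp[ti] & cmap$replicate == r]
        if (length(hit) == 0L)
          stop("design error: no sample column for cell (condition=", cond,
               ", time=", tp[ti], ", replicate=", r, ")")
        if (length(hit) > 1L)
          stop("design error: duplicated sample columns for cell (condition=",
               cond, ", time=", tp[ti], ", replicate=", r, "): ",
               paste(hit, collapse = ", "))
        vals[, r, ti] <- mat[, hit]
      }
    }
    if (anyNA(vals)) {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("validation error: missing value in condition '", cond,
           "' at feature '", feature_ids[bad[1L]], "' (replicate ", bad[2L],
           ", time index ", bad[3L], "); no imputation is performed")
    }
    tensors[[cond]] <- condition_tensor(cond, vals, feature_ids)
  }

  if (!design_balanced(design)) {
    warning("unequal replicate counts across conditions; replicates ",
            "summarized by mean (R = 1) to keep emission dimension defined")
    tensors <- lapply(tensors, summarize_replicates, method = "mean")
  } else if (design$replicate_summary != "none") {
    tensors <- lapply(tensors, summarize_replicates,
                      method = design$replicate_summary)
  }
  tensors
}

read_matrix_table <- function(matrix_file) {
  sep <- if (grepl("\\.csv$", matrix_file, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(matrix_file, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("parse error: expression table needs a feature-id column plus ",
         "at least one sample column")
  feature_ids <- tab[[1L]]
  if (anyDuplicated(feature_ids))
    stop("validation error: duplicated feature identifiers in column 1")
  body <- tab[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(feature_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & body[[j]] != "")
    if (length(bad))
      stop("parse error: non-numeric entry '", body[[j]][bad[1L]],
           "' at row '", feature_ids[bad[1L]], "', column '",
           colnames(body)[j], "'")
    mat[, j] <- v
  }
  list(matrix = mat, feature_ids = feature_ids)
}

read_column_map <- function(column_map) {
  if (is.character(column_map) && length(column_map) == 1L)
    column_map <- utils::read.table(column_map, header = TRUE, sep = "\t",
                                    check.names = FALSE, quote = "",
                                    comment.char = "",
                                    stringsAsFactors = FALSE)
  need <- c("sample", "condition", "time", "replicate")
  if (!is.data.frame(column_map) || !all(need %in% names(column_map)))
    stop("column_map must be a data frame (or TSV) with columns: ",
         paste(need, collapse = ", "))
  column_map$sample <- as.character(column_map$sample)
  column_map$condition <- as.character(column_map$condition)
  column_map$time <- as.numeric(column_map$time)
  column_map$replicate <- as.integer(column_map$replicate)
  if (anyDuplicated(column_map$sample))
    stop("design error: duplicated sample names in column_map")
  column_map
}

#' Write per-condition tensors back to a delimited expression matrix
#'
#' Inverse of [load_expression()]: flattens tensors to a single table with
#' sample columns named `<condition>_t<time>_r<replicate>` and writes the
#' matching column map, so the files round-trip through the loader.
#'
#' @param tensors Named list of [condition_tensor()] objects.
#' @param design The [experiment_design()] the tensors follow.
#' @param matrix_file Output TSV path.
#' @param column_map_file Output column-map TSV path (optional).
#' @return Invisibly, the column-map data frame.
#' @export
write_expression <- function(tensors, design, matrix_file,
                             column_map_file = NULL) {
  cols <- list(); cmap <- list()
  for (cond in design$conditions) {
    ten <- tensors[[cond]]
    d <- dim(ten$values)
    for (ti in seq_len(d[3L])) {
      for (r in seq_len(d[2L])) {
        nm <- sprintf("%s_t%s_r%d", cond,
                      format(design$time_points[ti], trim = TRUE), r)
        cols[[nm]] <- ten$values[, r, ti]
        cmap[[nm]] <- data.frame(sample = nm, condition = cond,
                                 time = design$time_points[ti],
                                 replicate = r)
      }
    }
  }
  out <- data.frame(feature_id = tensors[[1L]]$feature_ids, cols,
                    check.names = FALSE)
  utils::write.table(format_numeric_df(out), matrix_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmap <- do.call(rbind, cmap)
  rownames(cmap) <- NULL
  if (!is.null(column_map_file))
    utils::write.table(cmap, column_map_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(cmap)
}

# fixed-format numbers so identical runs write identical bytes
format_numeric_df <- function(df, digits = 10) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  df
}
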
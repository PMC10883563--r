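#' Feature matrix objects
#'
#' A `feature_matrix` is the fully preprocessed representation of one video:
#' a `46 x n_frames` numeric matrix (nominally `46 x 4500` at 25 fps for a
#' 3-minute video). Rows 1-36 are the x and y coordinates of the 18 body
#' points in infant unit lengths (body-aligned, mid-hip-centred), rows 37-46
#' the 10 joint angles in radians; row names come from [feature_row_names()].
#'
#' @param values Numeric matrix with 46 rows and no missing values.
#' @param video_id Video identifier.
#' @param fps Nominal frame rate of the resampled series (default 25).
#' @param n_frames Expected number of columns (default 4500); used for
#'   validation.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, video_id, fps = 25, n_frames = ncol(values)) {
  values <- as.matrix(values)
  if (nrow(values) != 46)
    stop("feature matrix must have exactly 46 rows, got ", nrow(values))
  if (!is.na(n_frames) && ncol(values) != n_frames)
    stop("feature matrix must have ", n_frames, " frames, got ", ncol(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature matrix contains missing or non-finite values")
  ang <- values[37:46, , drop = FALSE]
  if (min(ang) < -1e-9 || max(ang) > pi + 1e-9)
    stop("joint-angle rows must lie in [0, pi]")
  rownames(values) <- feature_row_names()
  structure(list(video_id = as.character(video_id), fps = fps,
                 values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: 46 x %d @ %g fps\n",
              x$video_id, ncol(x$values), x$fps))
  invisible(x)
}

#' Write / read a feature matrix
#'
#' Feature matrices are stored as self-describing tab-separated text with
#' `#key value` metadata lines (video_id, fps, row order) followed by one row
#' per feature. Values are formatted with 17 significant digits, so the
#' round-trip is bit-lossless for doubles.
#'
#' @param fm A [feature_matrix()].
#' @param path File path (`.tsv`).
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- c(paste0("#video_id\t", fm$video_id),
            paste0("#fps\t", sprintf("%.17g", fm$fps)),
            paste0("#n_frames\t", ncol(fm$values)))
  rows <- apply(fm$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(c(meta, paste(rownames(fm$values), rows, sep = "\t")), path)
  invisible(path)
}

#' @param n_frames Expected frame count for validation (default 4500; `NA`
#'   accepts any length).
#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, n_frames = 4500) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- strsplit(sub("^#", "", lines[meta_idx]), "\t")
  meta <- stats::setNames(vapply(meta, `[`, "", 2), vapply(meta, `[`, "", 1))
  body <- strsplit(lines[-meta_idx], "\t")
  if (length(body) != 46)
    stop("feature matrix file must have 46 data rows, got ", length(body))
  labels <- vapply(body, `[`, "", 1)
  if (!identical(labels, feature_row_names()))
    stop("feature matrix rows are not in canonical order")
  vals <- t(vapply(body, function(r) as.numeric(r[-1]),
                   numeric(length(body[[1]]) - 1)))
  stored_n <- as.integer(meta[["n_frames"]])
  if (!is.na(stored_n) && stored_n != ncol(vals))
    stop("frame count in header (", stored_n, ") does not match data (",
         ncol(vals), ")")
  feature_matrix(vals, video_id = meta[["video_id"]],
                 fps = as.numeric(meta[["fps"]]), n_frames = n_frames)
}
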
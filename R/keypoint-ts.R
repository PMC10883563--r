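#' Keypoint timeseries objects
#'
#' A `keypoint_ts` holds the raw per-frame output of a pose-estimation model
#' for one video: x and y pixel coordinates (image convention: origin at the
#' top-left corner, y increases downward) and a prediction confidence in
#' `[0, 1]` for each of the 18 canonical body points (see [body_points()]).
#' Missing coordinates are `NA`, never sentinel pixel values.
#'
#' @param x,y,confidence Numeric matrices `n_frames x 18`, columns in
#'   [body_points()] order (column names are set from it).
#' @param video_id Single string identifying the video.
#' @param fps Frames per second of the native recording (positive).
#' @return An object of class `keypoint_ts` with elements `video_id`, `fps`,
#'   `x`, `y`, `confidence`, `n_frames`.
#' @export
keypoint_ts <- function(video_id, fps, x, y, confidence) {
  x <- as.matrix(x); y <- as.matrix(y); confidence <- as.matrix(confidence)
  np <- length(body_points())
  if (ncol(x) != np || ncol(y) != np || ncol(confidence) != np)
    stop("x, y and confidence must each have ", np, " columns")
  if (nrow(x) != nrow(y) || nrow(x) != nrow(confidence))
    stop("x, y and confidence must share the same number of frames")
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  cv <- confidence[is.finite(confidence)]
  if (length(cv) && (min(cv) < 0 || max(cv) > 1))
    stop("confidence values must lie in [0, 1]")
  dimnames(x) <- dimnames(y) <- dimnames(confidence) <-
    list(NULL, body_points())
  structure(
    list(video_id = as.character(video_id), fps = fps,
         x = x, y = y, confidence = confidence, n_frames = nrow(x)),
    class = "keypoint_ts")
}

#' @export
print.keypoint_ts <- function(x, ...) {
  lab <- mean(!is.na(x$x))
  cat(sprintf("<keypoint_ts> %s: %d frames @ %.4g fps, %.1f%% labelled\n",
              x$video_id, x$n_frames, x$fps, 100 * lab))
  invisible(x)
}

#' Read a pose-estimation keypoint table
#'
#' Reads per-frame keypoint CSV exports in either of the two dialects common
#' for pose-estimation tools: a three-row header (scorer / bodyparts / coords,
#' with an index column) or a flat one-row header with columns named
#' `part_x`, `part_y`, `part_likelihood` (or `_confidence`). Body part names
#' are matched case-insensitively against [body_points()] plus a configurable
#' synonym map.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the source video (the table itself does not
#'   carry it).
#' @param video_id Video identifier; defaults to the file name without
#'   extension.
#' @param synonyms Named list mapping canonical body point names to accepted
#'   aliases; defaults to a built-in map.
#' @return A [keypoint_ts()].
#' @export
read_keypoints <- function(path, fps, video_id = NULL,
                           synonyms = .default_synonyms()) {
  if (is.null(video_id))
    video_id <- sub("\\.[^.]*$", "", basename(path))
  head3 <- readLines(path, n = 3)
  if (length(head3) < 1) stop("empty keypoint table: ", path)
  f1 <- strsplit(head3[1], ",")[[1]]
  three_row <- length(head3) >= 3 &&
    .squash(f1[1]) %in% c("scorer", "") &&
    .squash(strsplit(head3[2], ",")[[1]][1]) == "bodyparts"
  if (three_row) {
    parts_row <- strsplit(head3[2], ",")[[1]]
    coords_row <- strsplit(head3[3], ",")[[1]]
    dat <- utils::read.csv(path, skip = 3, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(dat) != length(coords_row))
      stop("malformed three-row header at line 3: expected ",
           length(coords_row), " columns, data has ", ncol(dat))
    # first column is the frame index
    part_of <- parts_row[-1]; coord_of <- .squash(coords_row[-1])
    vals <- as.matrix(dat[, -1, drop = FALSE])
  } else {
    dat <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
    nm <- names(dat)
    drop <- .squash(nm) %in% c("frame", "index", "")
    dat <- dat[, !drop, drop = FALSE]; nm <- names(dat)
    m <- regmatches(nm, regexec("^(.*)[_. ](x|y|likelihood|confidence)$",
                                nm, ignore.case = TRUE))
    bad <- which(vapply(m, length, 1L) != 3)
    if (length(bad))
      stop("malformed flat header at line 1: cannot parse column(s) ",
           paste(sprintf("'%s'", nm[bad]), collapse = ", "))
    part_of <- vapply(m, `[`, "", 2)
    coord_of <- tolower(vapply(m, `[`, "", 3))
    coord_of[coord_of == "confidence"] <- "likelihood"
    vals <- as.matrix(dat)
  }
  coord_of[coord_of %in% c("likelihood", "confidence", "p")] <- "likelihood"
  parts <- unique(part_of)
  map <- .match_parts(parts, synonyms)   # canonical -> header name
  n <- nrow(vals)
  pick <- function(part, coord) {
    j <- which(part_of == part & coord_of == coord)
    if (length(j) != 1)
      stop("body part '", part, "' lacks a unique '", coord, "' column")
    as.numeric(vals[, j])
  }
  xm <- sapply(map, pick, coord = "x")
  ym <- sapply(map, pick, coord = "y")
  cm <- sapply(map, pick, coord = "likelihood")
  if (n == 1) { xm <- t(xm); ym <- t(ym); cm <- t(cm) }
  keypoint_ts(video_id, fps, xm, ym, cm)
}

#' Write a keypoint timeseries as a three-row-header CSV
#'
#' Writes the standard pose-estimation export dialect (scorer / bodyparts /
#' coords header rows), readable back with [read_keypoints()].
#'
#' @param ts A [keypoint_ts()].
#' @param path Output file path.
#' @param scorer Scorer tag placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(ts, path, scorer = "gmascreen") {
  bp <- body_points()
  header1 <- paste(c("scorer", rep(scorer, 3 * length(bp))), collapse = ",")
  header2 <- paste(c("bodyparts", rep(bp, each = 3)), collapse = ",")
  header3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(bp))),
                   collapse = ",")
  cols <- vector("list", 3 * length(bp))
  for (i in seq_along(bp)) {
    cols[[3 * i - 2]] <- ts$x[, i]
    cols[[3 * i - 1]] <- ts$y[, i]
    cols[[3 * i]] <- ts$confidence[, i]
  }
  mat <- do.call(cbind, cols)
  body <- apply(cbind(seq_len(nrow(mat)) - 1, mat), 1, function(r)
    paste(ifelse(is.na(r), "", sprintf("%.17g", r)), collapse = ","))
  writeLines(c(header1, header2, header3, body), path)
  invisible(path)
}
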
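#' The canonical 18-point infant body point set
#'
#' A single ordered vector of body point names used everywhere in the package:
#' keypoint tables, feature-matrix rows, the synthetic simulator and the
#' saliency summaries all derive their ordering from this function. The points
#' are the landmarks typically annotated on supine infant videos for General
#' Movements screening: crown, chin, eyes, shoulders, elbows, wrists, hips,
#' knees, heels and big toes.
#'
#' @return Character vector of length 18, in fixed order.
#' @export
#' @examples
#' body_points()
body_points <- function() {
  c("crown", "chin",
    "left_eye", "right_eye",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_heel", "right_heel",
    "left_bigtoe", "right_bigtoe")
}

#' @rdname body_points
#' @details `feature_row_names()` gives the 46 row labels of a preprocessed
#'   feature matrix: x then y per body point (36 rows), followed by the 10
#'   joint angles (left/right shoulder, elbow, hip, knee, ankle).
#' @export
feature_row_names <- function() {
  bp <- body_points()
  coords <- as.vector(rbind(paste0(bp, "_x"), paste0(bp, "_y")))
  joints <- c("shoulder", "elbow", "hip", "knee", "ankle")
  angles <- unlist(lapply(joints, function(j) paste0(c("left_", "right_"), j, "_angle")))
  c(coords, angles)
}

# left/right mirror pairs, used by the simulator's symmetry checks
.bp_pairs <- function() {
  bp <- body_points()
  lefts <- grep("^left_", bp, value = TRUE)
  cbind(left = lefts, right = sub("^left_", "right_", lefts))
}

# default synonym map for keypoint-table headers: canonical name -> accepted
# aliases (case-insensitive; non-alphanumerics are squashed before matching)
.default_synonyms <- function() {
  list(
    crown = c("crown", "head", "headtop", "tophead"),
    chin = c("chin", "jaw"),
    left_eye = c("lefteye", "eyel", "leye"),
    right_eye = c("righteye", "eyer", "reye"),
    left_shoulder = c("leftshoulder", "shoulderl", "lshoulder"),
    right_shoulder = c("rightshoulder", "shoulderr", "rshoulder"),
    left_elbow = c("leftelbow", "elbowl", "lelbow"),
    right_elbow = c("rightelbow", "elbowr", "relbow"),
    left_wrist = c("leftwrist", "wristl", "lwrist", "lefthand"),
    right_wrist = c("rightwrist", "wristr", "rwrist", "righthand"),
    left_hip = c("lefthip", "hipl", "lhip"),
    right_hip = c("righthip", "hipr", "rhip"),
    left_knee = c("leftknee", "kneel", "lknee"),
    right_knee = c("rightknee", "kneer", "rknee"),
    left_heel = c("leftheel", "heell", "lheel", "leftankle"),
    right_heel = c("rightheel", "heelr", "rheel", "rightankle"),
    left_bigtoe = c("leftbigtoe", "bigtoel", "ltoe", "toel", "lefttoe",
                    "leftfoot"),
    right_bigtoe = c("rightbigtoe", "bigtoer", "rtoe", "toer", "righttoe",
                     "rightfoot")
  )
}

.squash <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# resolve arbitrary header part names onto the canonical set; returns a named
# character vector canonical -> header name, erroring on missing parts
.match_parts <- function(parts, synonyms = .default_synonyms()) {
  sq <- .squash(parts)
  out <- character(0)
  for (canon in body_points()) {
    hit <- which(sq %in% .squash(c(canon, synonyms[[canon]])))
    if (length(hit) == 0) out[canon] <- NA_character_ else out[canon] <- parts[hit[1]]
  }
  missing <- names(out)[is.na(out)]
  if (length(missing) > 0) {
    stop("keypoint table is missing required body point(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out
}
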
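#' Keypoint geometry checks
#'
#' Two geometric tests on 2-D skeletal keypoints (world coordinates,
#' horizontal `u`, vertical `v` increasing upward) decide when the
#' subject's posture is good enough to calibrate against:
#' `is_vertical()` checks that the head-neck segment is perpendicular to
#' the ground (side profile, no kyphotic slouch), `is_horizontal()` that
#' the shoulder line is parallel to the ground (frontal profile, no
#' lateral tilt). Both accept a small angular tolerance.
#'
#' @param head,neck,left_shoulder,right_shoulder 2-D points: numeric
#'   vectors `c(u, v)` (a third depth coordinate, if present, is
#'   ignored).
#' @param tol_deg angular tolerance in degrees; default 2.
#' @return Logical scalar.
#' @export
#' @examples
#' is_vertical(head = c(0, 2), neck = c(0, 1))        # TRUE
#' is_horizontal(c(-1, 1), c(1, 1.5))                  # FALSE at 2 deg
is_vertical <- function(head, neck, tol_deg = 2.0) {
  du <- head[1] - neck[1]
  dv <- head[2] - neck[2]
  if (du == 0 && dv == 0) {
    stop("degenerate geometry: head and neck points coincide", call. = FALSE)
  }
  angle_from_vertical <- atan2(abs(du), abs(dv)) * 180 / pi
  angle_from_vertical <= tol_deg
}

#' @rdname is_vertical
#' @export
is_horizontal <- function(left_shoulder, right_shoulder, tol_deg = 2.0) {
  du <- right_shoulder[1] - left_shoulder[1]
  dv <- right_shoulder[2] - left_shoulder[2]
  if (du == 0 && dv == 0) {
    stop("degenerate geometry: shoulder points coincide", call. = FALSE)
  }
  angle_from_horizontal <- atan2(abs(dv), abs(du)) * 180 / pi
  angle_from_horizontal <= tol_deg
}

#' Read / write keypoint frames
#'
#' Keypoint CSV dialect: header
#' `t_s,head_u,head_v,neck_u,neck_v,lsh_u,lsh_v,rsh_u,rsh_v`, one frame
#' per row, coordinates in world units with `v` increasing upward.
#'
#' @param path CSV path.
#' @return `read_keypoints()`: data frame of class `keypoint_frames` with
#'   the nine columns above.
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) {
    stop("keypoints file not found: ", path, call. = FALSE)
  }
  kp <- utils::read.csv(path, strip.white = TRUE)
  required <- c("t_s", "head_u", "head_v", "neck_u", "neck_v",
                "lsh_u", "lsh_v", "rsh_u", "rsh_v")
  missing <- setdiff(required, names(kp))
  if (length(missing) > 0L) {
    stop("keypoints CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(kp[required])) {
    stop("keypoints CSV contains missing or non-numeric values",
         call. = FALSE)
  }
  if (any(kp$head_v <= kp$neck_v)) {
    warning("some frames have head at or below neck height; ",
            "subject may not be standing", call. = FALSE)
  }
  class(kp) <- c("keypoint_frames", "data.frame")
  kp
}

#' @rdname read_keypoints
#' @param frames data frame with the keypoint columns.
#' @export
write_keypoints <- function(frames, path) {
  cols <- c("t_s", "head_u", "head_v", "neck_u", "neck_v",
            "lsh_u", "lsh_v", "rsh_u", "rsh_v")
  stopifnot(all(cols %in% names(frames)))
  out <- as.data.frame(lapply(as.data.frame(frames)[cols], format_num))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
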
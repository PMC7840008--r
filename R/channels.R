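#' Body segment and channel naming scheme
#'
#' Full-body recordings follow an IMU-suit convention: 17 body segments,
#' each with three rotational degrees of freedom extracted as Euler angles
#' (Z = flexion/extension, X = abduction/adduction, Y = internal/external
#' rotation), giving 51 angle channels. Channel names are
#' `<segment>_<dof>` with `dof` one of `"z"`, `"x"`, `"y"`, e.g.
#' `right_shoulder_z`.
#'
#' @return `evr_segments()` returns the 17 segment names;
#'   `evr_channels()` returns the 51 channel names in canonical order
#'   (segment-major, DoF order z, x, y).
#' @examples
#' length(evr_channels())  # 51
#' @export
evr_segments <- function() {
  c("pelvis", "l5", "l3", "t12", "t8", "neck", "head",
    "right_shoulder", "right_elbow", "right_wrist",
    "left_shoulder", "left_elbow", "left_wrist",
    "right_hip", "right_knee", "left_hip", "left_knee")
}

#' @rdname evr_segments
#' @export
evr_channels <- function() {
  as.vector(t(outer(evr_segments(), c("z", "x", "y"), paste, sep = "_")))
}

#' Channel names belonging to a set of segments
#'
#' @param segments character vector of segment names.
#' @return character vector of `segment_dof` channel names (3 per segment).
#' @export
segment_channels <- function(segments) {
  bad <- setdiff(segments, evr_segments())
  if (length(bad) > 0) {
    stop("unknown segment(s): ", paste(bad, collapse = ", "))
  }
  as.vector(t(outer(segments, c("z", "x", "y"), paste, sep = "_")))
}
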
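#' COCO-17 keypoint names
#'
#' The fixed anatomical keypoint order used throughout the package: the
#' 17-landmark COCO convention (nose, eyes, ears, shoulders, elbows, wrists,
#' hips, knees, ankles), which is what the common 2D pose estimators
#' (HRNet-family networks among them) emit. All pose tables must list
#' keypoints in this order, indexed 0 to 16.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' coco17_keypoints()
coco17_keypoints <- function() {
  c(
    "nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle"
  )
}

N_KEYPOINTS <- 17L
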
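#' Joint layout conventions
#'
#' Keypoint sequences use the 17-joint COCO ordering as emitted by common
#' pose estimators. For gait analysis the four face joints carrying no
#' locomotor information (both eyes, both ears) are dropped, leaving 13
#' joints whose order is frozen here: the reduced layout is the COCO order
#' with positions 2-5 removed.
#'
#' @format `coco17_joints` and `reduced13_joints` are character vectors of
#'   joint names in storage order.
#' @name joint-layouts
NULL

#' @rdname joint-layouts
#' @export
coco17_joints <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle"
)

#' @rdname joint-layouts
#' @export
reduced13_joints <- coco17_joints[-(2:5)]

# index of the retained joints within the coco17 ordering
.reduced13_idx <- which(coco17_joints %in% reduced13_joints)

.joint_names <- function(layout) {
  switch(layout,
    coco17 = coco17_joints,
    reduced13 = reduced13_joints,
    stop("unknown joint layout: ", layout, call. = FALSE)
  )
}

.n_joints <- function(layout) length(.joint_names(layout))

.joint_index <- function(seq, name) {
  i <- match(name, .joint_names(seq$joint_layout))
  if (is.na(i)) {
    stop("joint '", name, "' not present in layout '", seq$joint_layout, "'",
      call. = FALSE
    )
  }
  i
}
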
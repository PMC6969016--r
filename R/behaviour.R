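#' Behaviour class vocabulary
#'
#' The classifier operates on a five-class vocabulary: four scent-marking
#' postures plus a catch-all `"other"` class. Annotation files may use finer
#' "other" labels (walk, run, jump, stand, lie, sit, shake) which
#' [collapse_other()] folds into `"other"` before analysis.
#'
#' @return Character vector of class names.
#' @export
behaviour_classes <- function() c(scent_classes(), "other")

#' @rdname behaviour_classes
#' @export
scent_classes <- function() {
  c("left_leg", "right_leg", "squat_urinate", "squat_defaecate")
}

#' @rdname behaviour_classes
#' @export
other_fine_labels <- function() {
  c("walk", "run", "jump", "stand", "lie", "sit", "shake")
}

#' Collapse fine-grained "other" behaviour labels
#'
#' Maps the fine locomotion/resting labels onto the general `"other"` class and
#' validates that every resulting label belongs to the vocabulary.
#'
#' @param labels character vector of behaviour labels.
#' @return Character vector over [behaviour_classes()].
#' @export
collapse_other <- function(labels) {
  labels <- as.character(labels)
  labels[labels %in% other_fine_labels()] <- "other"
  bad <- setdiff(unique(labels), behaviour_classes())
  if (length(bad)) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "))
  }
  labels
}

#' @rdname collapse_other
#' @param x character vector of class names.
#' @export
is_scent_class <- function(x) x %in% scent_classes()
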
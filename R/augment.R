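#' Augmentation plan for one limited class
#'
#' @param pairing A [closest_class()] `transfer_pairing`.
#' @param target_count Number of synthetic sequences to add.
#' @param washout Frames dropped at the start of each transformed sequence.
#' @return An `augmentation_plan`.
#' @export
augmentation_plan <- function(pairing, target_count, washout = 10L) {
  stopifnot(inherits(pairing, "transfer_pairing"), target_count >= 0,
            washout >= 0)
  structure(
    list(pairing = pairing, target_count = as.integer(target_count),
         washout = as.integer(washout), pairing_strategy = "random_truncate"),
    class = "augmentation_plan"
  )
}

#' Augment a limited class with transformed donor sequences
#'
#' Transforms donor training sequences through the trained reservoir and
#' appends the results as synthetic limited-class sequences until
#' `target_count` new items exist. Original sequences are never modified;
#' when the donor holds fewer clips than requested, donors are resampled
#' with replacement (with a message).
#'
#' @param corpus List of [feature_seq()] objects (training folds only).
#' @param plan An [augmentation_plan()].
#' @param rt The trained `reservoir_transform` for this pairing.
#' @param seed Integer seed for donor resampling order.
#' @return `corpus` with the synthetic sequences appended.
#' @export
augment_class <- function(corpus, plan, rt, seed = 1L) {
  if (plan$target_count == 0L) return(corpus)
  labels <- vapply(corpus, function(s) s$label %||% NA_character_, "")
  donors <- corpus[labels == plan$pairing$donor_class &
                     !vapply(corpus, `[[`, FALSE, "synthetic")]
  if (length(donors) == 0) stop("no donor sequences for class ",
                                plan$pairing$donor_class)
  local_seed(seed)
  idx <- if (plan$target_count <= length(donors)) {
    sample.int(length(donors), plan$target_count)
  } else {
    message("donor class ", plan$pairing$donor_class, " has ",
            length(donors), " clips; resampling with replacement to reach ",
            plan$target_count)
    sample.int(length(donors), plan$target_count, replace = TRUE)
  }
  synth <- lapply(seq_along(idx), function(j) {
    s <- apply_transfer(rt, donors[[idx[j]]], label = plan$pairing$limited_class)
    s$clip_id <- sprintf("%s_aug%02d", s$clip_id, j)
    s
  })
  c(corpus, synth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
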
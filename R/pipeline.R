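# End-to-end scoring: photograph -> hand mask -> finger regions -> score.

#' Score one photograph frame
#'
#' Runs the full per-frame pipeline: optional square resize, hand
#' segmentation (classical fallback or a trained segmenter), landmark
#' rescaling onto the mask grid, per-finger region extraction and the
#' redness score over the non-thumb digits.
#'
#' @param image H x W x 3 array, intensities in \[0, 255\].
#' @param landmarks A landmark data frame (one hand) or a list of them
#'   (one per hand in the frame). Normalized coordinates are rescaled
#'   automatically; pixel coordinates are assumed to refer to the original
#'   frame and are mapped through the resize.
#' @param segmenter `NULL` for the classical segmenter, or an
#'   `artix_segmenter` from [train_segmenter()].
#' @param side Working resolution; `NULL` keeps the frame as-is when
#'   already square, otherwise resizes to 512.
#' @param sigma,weights,min_pixels Passed to [artix_score()].
#' @param timepoint_label Optional label stored in the result.
#' @return An `artix_score`.
#' @export
score_frame <- function(image, landmarks, segmenter = NULL, side = NULL,
                        sigma = 2, weights = score_weights(),
                        min_pixels = 25L, timepoint_label = NULL) {
  assert_rgb_image(image)
  d <- dim(image)
  if (is.null(side)) side <- if (d[1] == d[2]) d[1] else 512L
  src_shape <- c(d[1], d[2])
  work <- resize_square(image, side)
  mask <- if (is.null(segmenter)) segment_hand_classical(work)
          else segment_hand_model(segmenter, work)
  if (is.data.frame(landmarks)) landmarks <- list(landmarks)
  regions <- do.call(c, lapply(landmarks, function(lms) {
    lms <- assert_landmarks(lms)
    lms <- if (isTRUE(all(lms$normalized))) {
      rescale_landmarks(lms, dim(mask))
    } else {
      rescale_landmarks(lms, dim(mask), source_shape = src_shape)
    }
    segment_fingers(mask, lms)
  }))
  artix_score(work, regions, sigma = sigma, weights = weights,
              min_pixels = min_pixels, timepoint_label = timepoint_label)
}

#' Score a rendered cold-challenge session
#'
#' Applies [score_frame()] to every rendered timepoint of a session
#' simulated with `render = TRUE`, using the generator's ground-truth
#' landmarks, and returns the recovered per-timepoint score series next to
#' the simulated one.
#'
#' @param session A `challenge_session` carrying rendered images.
#' @param segmenter Optional trained segmenter (classical fallback
#'   otherwise).
#' @param ... Passed to [score_frame()].
#' @return Data frame with columns `timepoint_label`, `artix_simulated`,
#'   `artix_scored`.
#' @export
score_session <- function(session, segmenter = NULL, ...) {
  stopifnot(inherits(session, "challenge_session"))
  if (is.null(session$images)) {
    artix_error("artix_bad_input",
                "session carries no rendered images; simulate with render = TRUE")
  }
  labels <- names(session$images)
  scored <- vapply(labels, function(tp) {
    hands <- session$images[[tp]]
    vals <- vapply(hands, function(h) {
      score_frame(h$image, h$landmarks, segmenter = segmenter,
                  timepoint_label = tp, ...)$value
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  data.frame(timepoint_label = labels,
             artix_simulated = unname(session$artix[labels]),
             artix_scored = unname(scored),
             stringsAsFactors = FALSE)
}
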
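# Per-seed classification maps: every pixel of a seed is colored by the
# seed's predicted variety. Default palette: background black, classes
# red / green / blue.

#' Paint a classification map from ROI predictions
#'
#' @param rois a [label_rois()] result or bare label matrix.
#' @param predictions integer class per ROI label `1..K` (vector in label
#'   order, or data.frame with columns `id`/`label` and `predicted`/`class`).
#' @return integer matrix of class `classification_map`; background 0.
#' @export
paint_map <- function(rois, predictions) {
  labels <- if (inherits(rois, "roi_label_map")) rois$labels else rois
  K <- max(labels)
  if (is.data.frame(predictions)) {
    idc <- intersect(c("id", "label"), names(predictions))[1L]
    prc <- intersect(c("predicted", "class"), names(predictions))[1L]
    if (is.na(idc) || is.na(prc))
      stop("prediction data.frame needs id/label and predicted/class columns")
    pred <- rep(NA_integer_, K)
    pred[predictions[[idc]]] <- as.integer(predictions[[prc]])
  } else {
    pred <- rep(NA_integer_, K)
    pred[seq_along(predictions)] <- as.integer(predictions)
  }
  if (K > 0L && anyNA(pred))
    stop("missing prediction for label(s): ",
         paste(which(is.na(pred)), collapse = ", "))
  map <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels != 0L
  map[nz] <- pred[labels[nz]]
  class(map) <- c("classification_map", class(map))
  map
}

#' Object-level map accuracy
#'
#' @param predictions integer predicted class per ROI.
#' @param truth integer true class per ROI, same length.
#' @return list with `correct`, `total`, `fraction` and `percent`
#'   (to one decimal).
#' @export
map_accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("ROI count mismatch: ", length(predictions), " predictions vs ",
         length(truth), " truths")
  correct <- sum(as.integer(predictions) == as.integer(truth))
  total <- length(truth)
  frac <- if (total == 0L) NaN else correct / total
  list(correct = correct, total = total, fraction = frac,
       percent = round(100 * frac, 1))
}
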
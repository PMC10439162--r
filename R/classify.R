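#' Classify segments by nearest labeled prototype
#'
#' Projects each segment's z-normalized feature vector into the prototype
#' set's PC space and assigns the label of the Euclidean-nearest centroid.
#' New data are z-normalized with the statistics of their *own* dataset
#' (mirroring the per-individual normalization used when the prototypes
#' were built); set `norm = "prototype"` to reuse the prototype dataset's
#' statistics instead for sensitivity analysis.
#'
#' @param object A `state_prototypes` object.
#' @param newdata A `segment_set`, or a `feature_matrix` (raw or already
#'   z-normalized).
#' @param norm `"own"` (default) or `"prototype"`: which normalization
#'   statistics to apply when `newdata` is raw.
#' @param ... Unused.
#' @return A data.frame of class `state_predictions` with columns
#'   `segment_index`, `predicted_label`, `distance`, `true_label` (NA when
#'   unknown), plus attributes `scores` (PC points) and
#'   `prototype_origin`. Distance ties are broken toward the lower label
#'   with a warning.
#' @examples
#' \donttest{
#' ss <- simulate_type_set(25, seed = 1)
#' proto <- fit_prototypes(ss, seed = 1)
#' head(predict(proto, ss))
#' }
#' @export
predict.state_prototypes <- function(object, newdata,
                                     norm = c("own", "prototype"), ...) {
  norm <- match.arg(norm)
  if (nrow(object$centroids) == 0) stop("empty prototype set")
  fm <- if (inherits(newdata, "feature_matrix")) newdata
        else segment_features(newdata, "newdata")
  fmz <- if (isTRUE(attr(fm, "normalized"))) fm
         else if (norm == "own") znormalize(fm)
         else znormalize(fm, stats = object$projection$norm_stats)
  scores <- project_features(object, fmz)

  ord <- order(object$labels)          # tie-break toward the lower label
  cent <- object$centroids[ord, , drop = FALSE]
  labs <- object$labels[ord]
  d2 <- outer(rowSums(scores^2), rowSums(cent^2), "+") -
    2 * scores %*% t(cent)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  tied <- apply(d2, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1)
  if (any(tied))
    warning(sum(tied), " segment(s) equidistant from two prototypes: ",
            "assigned the lower label")

  out <- data.frame(segment_index = seq_len(nrow(scores)),
                    predicted_label = labs[nearest],
                    distance = dmin,
                    true_label = attr(fm, "labels") %||%
                      rep(NA_integer_, nrow(scores)))
  attr(out, "scores") <- scores
  attr(out, "prototype_origin") <- object$provenance$origin
  class(out) <- c("state_predictions", "data.frame")
  out
}

#' Write predictions to CSV
#' @param pred A `state_predictions` data.frame.
#' @param path Output file.
#' @export
write_predictions <- function(pred, path) {
  utils::write.csv(as.data.frame(pred)[, c("segment_index",
                                           "predicted_label", "distance")],
                   path, row.names = FALSE)
  invisible(path)
}
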
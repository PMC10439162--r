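#' Principal component projection of a normalized feature matrix
#'
#' PCA with a fixed number of components (four by default, which captures
#' the shared structure of the eleven features). Loadings are
#' sign-standardized so that the largest-magnitude entry of each column is
#' positive, making stored projections reproducible. Input must already be
#' z-normalized; the fit refuses more components than segments.
#'
#' @param fm A z-normalized `feature_matrix`.
#' @param n_components Number of retained components.
#' @return A `pc_projection`: list with `coefficients` (11 x k loadings),
#'   `explained_variance_ratio`, `scores` (segments x k), `center` (column
#'   means removed by the fit), `norm_stats` and `dataset_id` copied from
#'   the input.
#' @export
fit_pca <- function(fm, n_components = 4) {
  stopifnot(is.matrix(fm), nrow(fm) >= n_components)
  if (!isTRUE(attr(fm, "normalized")))
    warning("feature matrix does not appear to be z-normalized")
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  k <- n_components
  coef <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(coef, 2, function(v) sign(v[which.max(abs(v))]))
  coef <- sweep(coef, 2, flip, "*")
  scores <- sweep(fm, 2, pc$center, "-") %*% coef
  structure(list(coefficients = coef,
                 explained_variance_ratio =
                   pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
                 scores = scores,
                 center = pc$center,
                 norm_stats = attr(fm, "norm_stats"),
                 dataset_id = attr(fm, "dataset_id") %||% "dataset"),
            class = "pc_projection")
}

#' Project feature vectors into an existing PC space
#'
#' Multiplies z-normalized features by the stored PCA coefficients (after
#' removing the stored fit center). Features must be in canonical order
#' and normalized within their own dataset.
#'
#' @param proj A `pc_projection` (or a `state_prototypes` object, whose
#'   projection is used).
#' @param fm A z-normalized feature matrix or a single feature vector.
#' @return Matrix of PC scores (rows = segments).
#' @export
project_features <- function(proj, fm) {
  if (inherits(proj, "state_prototypes")) proj <- proj$projection
  stopifnot(inherits(proj, "pc_projection"))
  if (is.null(dim(fm))) fm <- matrix(fm, nrow = 1,
                                     dimnames = list(NULL, names(fm)))
  if (ncol(fm) != nrow(proj$coefficients))
    stop("feature count does not match the projection")
  if (is.matrix(fm) && nrow(fm) > 1) {
    mu <- colMeans(fm); sdev <- apply(fm, 2, stats::sd)
    if (any(abs(mu) > 0.1) || any(abs(sdev - 1) > 0.25))
      warning("input does not look z-normalized ",
              "(column means/SDs deviate from 0/1)")
  }
  sweep(unclass(fm), 2, proj$center, "-") %*% proj$coefficients
}

#' k-means clustering of PC scores
#'
#' Hartigan-Wong k-means with many random restarts (50 by default); the
#' restart with the smallest within-cluster sum of squares wins.
#' Reproducible when a seed is set by the caller or passed here.
#'
#' @param scores Segments x k score matrix.
#' @param k Number of clusters.
#' @param n_init Random restarts.
#' @param seed Optional seed set before initialization.
#' @return List with `centroids` (k x dims) and `assignments` (per row).
#' @export
kmeans_cluster <- function(scores, k = 4, n_init = 50, seed = NULL) {
  stopifnot(nrow(scores) >= k)
  if (nrow(unique(round(scores, 12))) < k)
    stop("fewer than k distinct points: clustering is degenerate")
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_init, iter.max = 100)
  list(centroids = unname(km$centers), assignments = unname(km$cluster),
       tot_withinss = km$tot.withinss)
}

#' Label cluster centroids by Voronoi voting of simulated segments
#'
#' Each simulated model segment (whose generating brain state is known) is
#' assigned to its nearest centroid in PC space; every centroid is then
#' labeled by majority vote of the model segments in its Voronoi region.
#' A centroid whose region is empty is dropped. If two centroids receive
#' the same label, only the one backed by more label-defining segments is
#' kept. Vote ties go to the lower label number and count ties to the
#' lower centroid index, each with a warning.
#'
#' @param centroids k x dims matrix of cluster centroids.
#' @param model_scores Model-segment points in the same PC space.
#' @param model_labels Integer true labels (1--4) of `model_scores` rows.
#' @return List with `centroids` (kept rows), `labels`, `n_vote_segments`
#'   (label-defining votes behind each kept centroid) and `region_sizes`
#'   (all voters in each kept centroid's Voronoi cell).
#' @export
match_centroids <- function(centroids, model_scores, model_labels) {
  stopifnot(nrow(model_scores) == length(model_labels),
            all(model_labels %in% 1:4))
  region <- nearest_index(model_scores, centroids)
  k <- nrow(centroids)
  region_n <- tabulate(region, nbins = k)
  lab <- rep(NA_integer_, k)
  votes <- integer(k)
  for (c in seq_len(k)) {
    in_region <- model_labels[region == c]
    if (length(in_region) == 0) next  # empty region: centroid dropped
    tab <- tabulate(in_region, nbins = 4)
    win <- which(tab == max(tab))
    if (length(win) > 1)
      warning("vote tie in centroid ", c, ": assigning lower label")
    lab[c] <- win[1]
    votes[c] <- max(tab)
  }
  if (all(is.na(lab)))
    stop("all Voronoi regions are empty: no prototypes could be labeled")
  keep <- logical(k)
  for (l in sort(unique(stats::na.omit(lab)))) {
    cand <- which(lab == l)
    best <- cand[which.max(votes[cand])]
    if (length(cand) > 1) {
      if (sum(votes[cand] == max(votes[cand])) > 1)
        warning("equal vote counts for label ", l,
                ": keeping the lower-index centroid")
      }
    keep[best] <- TRUE
  }
  list(centroids = centroids[keep, , drop = FALSE],
       labels = lab[keep],
       n_vote_segments = votes[keep],
       region_sizes = region_n[keep],
       n_voters = length(model_labels))
}

# Row index of the nearest centroid (Euclidean) for each point.
nearest_index <- function(points, centroids) {
  d2 <- outer(rowSums(points^2), rowSums(centroids^2), "+") -
    2 * points %*% t(centroids)
  max.col(-d2, ties.method = "first")
}

#' Fit labeled brain-state prototypes
#'
#' The central fitting step: from a dataset of segments (real or
#' simulated) it derives a set of up to four labeled prototype centroids
#' living in a four-dimensional PC space, against which any segment can be
#' classified with [predict.state_prototypes()].
#'
#' The pipeline is: z-normalize the dataset's feature matrix, fit a
#' four-component PCA, cluster the scores with k-means (k = 4), and label
#' the centroids by Voronoi voting of simulated model segments projected
#' into the same space (the model segments are z-normalized with their own
#' statistics first). For model-driven prototyping the dataset and the
#' voting set are the same 400 simulated segments.
#'
#' @param x A `segment_set` or a raw `feature_matrix` of the prototype
#'   dataset.
#' @param vote_set The labeled simulated segments used for centroid
#'   labeling: a `segment_set` or raw `feature_matrix` with labels. By
#'   default (`NULL`) `x` itself is used, which requires `x` to carry true
#'   labels (model-driven prototyping).
#' @param n_components Retained principal components.
#' @param k Number of k-means clusters.
#' @param n_init k-means restarts.
#' @param seed Seed for the clustering initialization (recorded in
#'   provenance).
#' @return A `state_prototypes` object: `centroids`, `labels`,
#'   `projection` (a `pc_projection`), `n_vote_segments`, `provenance`.
#' @examples
#' \donttest{
#' ss <- simulate_type_set(25, seed = 1)
#' proto <- fit_prototypes(ss, seed = 1)
#' predict(proto, ss)$predicted_label[1]
#' }
#' @export
fit_prototypes <- function(x, vote_set = NULL, n_components = 4, k = 4,
                           n_init = 50, seed = 1) {
  fm <- if (inherits(x, "feature_matrix")) x else segment_features(x, "prototype")
  if (isTRUE(attr(fm, "normalized")))
    stop("pass the raw feature matrix; normalization happens inside the fit")
  fmz <- znormalize(fm)
  proj <- fit_pca(fmz, n_components)
  cl <- kmeans_cluster(proj$scores, k = k, n_init = n_init, seed = seed)

  if (is.null(vote_set)) {
    vote_scores <- proj$scores
    vote_labels <- attr(fm, "labels")
    origin <- "model"
  } else {
    vfm <- if (inherits(vote_set, "feature_matrix")) vote_set
           else segment_features(vote_set, "model-votes")
    vote_labels <- attr(vfm, "labels")
    vfmz <- if (isTRUE(attr(vfm, "normalized"))) vfm else znormalize(vfm)
    vote_scores <- project_features(proj, vfmz)
    origin <- proj$dataset_id
  }
  if (any(is.na(vote_labels)))
    stop("the voting set must carry true brain-state labels")
  matched <- match_centroids(cl$centroids, vote_scores, vote_labels)

  structure(list(centroids = matched$centroids,
                 labels = matched$labels,
                 projection = proj,
                 n_vote_segments = matched$n_vote_segments,
                 region_sizes = matched$region_sizes,
                 provenance = list(origin = origin, seed = seed,
                                   k = k, n_init = n_init,
                                   n_segments = nrow(fm))),
            class = "state_prototypes")
}

#' @export
print.state_prototypes <- function(x, ...) {
  nm <- names(brain_state_labels())[x$labels]
  cat(sprintf("<state_prototypes> %d labeled prototypes in %d-PC space\n",
              nrow(x$centroids), ncol(x$centroids)))
  cat("  labels:", paste(sprintf("%s(%d votes)", nm, x$n_vote_segments),
                         collapse = ", "), "\n")
  cat(sprintf("  origin: %s; variance explained by %d PCs: %.1f%%\n",
              x$provenance$origin, ncol(x$centroids),
              100 * sum(x$projection$explained_variance_ratio)))
  invisible(x)
}

#' @export
summary.state_prototypes <- function(object, ...) {
  out <- list(
    n_prototypes = nrow(object$centroids),
    labels = stats::setNames(object$labels,
                             names(brain_state_labels())[object$labels]),
    explained_variance_ratio = object$projection$explained_variance_ratio,
    n_vote_segments = object$n_vote_segments,
    provenance = object$provenance)
  class(out) <- "summary.state_prototypes"
  out
}

#' @export
print.summary.state_prototypes <- function(x, ...) {
  cat("Brain-state prototype set\n")
  cat("  prototypes:", x$n_prototypes, "->",
      paste(names(x$labels), collapse = ", "), "\n")
  cat("  PC variance ratios:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "),
      sprintf("(total %.3f)\n", sum(x$explained_variance_ratio)))
  cat("  votes per prototype:", paste(x$n_vote_segments, collapse = ", "),
      "\n")
  cat("  origin:", x$provenance$origin, "| k-means seed:",
      x$provenance$seed, "\n")
  invisible(x)
}

#' @export
coef.state_prototypes <- function(object, ...) object$projection$coefficients

#' Plot prototypes and (optionally) classified segments in PC space
#'
#' Scatter of the first two principal components with the labeled
#' prototype centroids; when `newdata` is given, its segments are shown
#' colored by predicted state.
#'
#' @param x A `state_prototypes` object.
#' @param newdata Optional `segment_set`/raw `feature_matrix` to classify
#'   and overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.state_prototypes <- function(x, newdata = NULL, ...) {
  cols <- c("#3B6FB6", "#4FB06D", "#E3B13E", "#C0392B")
  sc <- x$projection$scores
  graphics::plot(sc[, 1], sc[, 2], col = "grey70", pch = 16, cex = 0.5,
                 xlab = "PC 1", ylab = "PC 2", ...)
  if (!is.null(newdata)) {
    pred <- predict(x, newdata)
    pts <- attr(pred, "scores")
    graphics::points(pts[, 1], pts[, 2], col = cols[pred$predicted_label],
                     pch = 1, cex = 0.7)
  }
  graphics::points(x$centroids[, 1], x$centroids[, 2], pch = 21, cex = 2,
                   bg = cols[x$labels], col = "black", lwd = 2)
  graphics::legend("topright", legend = names(brain_state_labels()),
                   pt.bg = cols, pch = 21, bty = "n")
  invisible(x)
}

#' Serialize a prototype set to JSON
#'
#' Writes feature order, normalization statistics, PCA coefficients,
#' explained variance ratios, centroids, labels and provenance as one JSON
#' document that [read_prototypes()] restores.
#'
#' @param proto A `state_prototypes` object.
#' @param path Output file.
#' @export
write_prototypes <- function(proto, path) {
  doc <- list(
    feature_names = feature_names(),
    norm_stats = proto$projection$norm_stats,
    pca_center = proto$projection$center,
    pca_coefficients = proto$projection$coefficients,
    explained_variance_ratio = proto$projection$explained_variance_ratio,
    centroids = proto$centroids,
    labels = proto$labels,
    n_vote_segments = proto$n_vote_segments,
    provenance = proto$provenance,
    tool = paste("epistates",
                 as.character(utils::packageVersion("epistates"))))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a prototype set written by [write_prototypes()]
#' @param path JSON file.
#' @return A `state_prototypes` object.
#' @export
read_prototypes <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  proj <- structure(list(
    coefficients = matrix(unlist(doc$pca_coefficients), ncol =
                            length(doc$explained_variance_ratio)),
    explained_variance_ratio = doc$explained_variance_ratio,
    scores = NULL,
    center = unlist(doc$pca_center),
    norm_stats = lapply(doc$norm_stats, unlist),
    dataset_id = doc$provenance$origin), class = "pc_projection")
  structure(list(centroids = matrix(unlist(doc$centroids),
                                    nrow = length(doc$labels)),
                 labels = as.integer(doc$labels),
                 projection = proj,
                 n_vote_segments = as.integer(doc$n_vote_segments),
                 provenance = doc$provenance),
            class = "state_prototypes")
}
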
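test_that("PCA projection is consistent, sign-fixed and variance-ordered", {
  ss <- small_type_set()
  fmz <- znormalize(segment_features(ss, "model"))
  proj <- fit_pca(fmz, 4)
  expect_equal(dim(proj$coefficients), c(11, 4))
  # loadings are orthonormal
  expect_equal(t(proj$coefficients) %*% proj$coefficients, diag(4),
               tolerance = 1e-8, ignore_attr = TRUE)
  evr <- proj$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12) && all(evr > 0) && sum(evr) <= 1)
  # sign convention: dominant loading entry positive
  expect_true(all(apply(proj$coefficients, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # projecting the fit's own data reproduces the fit scores
  expect_equal(project_features(proj, fmz), proj$scores,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-one feature matrices load entirely on the first component", {
  set.seed(4)
  base <- rnorm(30)
  fm <- outer(base, seq_len(11))          # perfectly collinear features
  colnames(fm) <- feature_names()
  fmz <- suppressWarnings(znormalize(fm))
  proj <- suppressWarnings(fit_pca(fmz, 4))
  expect_equal(proj$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_equal(proj$explained_variance_ratio[-1], numeric(3),
               tolerance = 1e-10)
})

test_that("k-means recovers well-separated blobs and beats random centroids", {
  set.seed(5)
  means <- rbind(c(0, 0, 0, 0), c(10, 0, 0, 0), c(0, 10, 0, 0),
                 c(0, 0, 10, 0))
  pts <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(50 * 4, sd = 0.5), 50, 4), 2, means[i, ], "+")))
  cl <- kmeans_cluster(pts, k = 4, seed = 1)
  ord <- oracle_nearest(means, cl$centroids)
  expect_equal(sort(ord), 1:4)                     # one centroid per blob
  expect_true(all(sqrt(rowSums((cl$centroids[ord, ] - means)^2))
                  < 3 * 0.5 / sqrt(50)))
  truth <- rep(1:4, each = 50)
  expect_equal(unname(table(truth, cl$assignments) > 0) |> rowSums(),
               rep(1, 4), ignore_attr = TRUE)      # perfect assignment
  # objective beats 100 random centroid sets
  rand_ss <- replicate(100, {
    cent <- pts[sample(nrow(pts), 4), ]
    sum((pts - cent[oracle_nearest(pts, cent), ])^2)
  })
  expect_true(all(cl$tot_withinss <= rand_ss))
  # k = 1 reduces to the grand mean
  one <- kmeans_cluster(pts, k = 1, seed = 1)
  expect_equal(as.numeric(one$centroids), colMeans(pts), tolerance = 1e-10)
  expect_error(kmeans_cluster(matrix(1, 10, 4), k = 4), "degenerate")
})

test_that("Voronoi voting labels centroids and partitions all voters", {
  set.seed(6)
  means <- diag(4) * 8
  scores <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(25 * 4, sd = 0.3), 25, 4), 2, means[i, ], "+")))
  labels <- rep(1:4, each = 25)
  m <- match_centroids(means, scores, labels)
  expect_equal(m$labels, 1:4)
  expect_equal(sum(m$region_sizes), m$n_voters)  # a true partition
  expect_equal(m$n_vote_segments, rep(25L, 4))
})

test_that("duplicate labels keep the better-supported centroid only", {
  # two centroids both in ictal territory with 30 vs 10 voters
  centroids <- rbind(c(0, 0, 0, 0), c(20, 0, 0, 0), c(0, 20, 0, 0),
                     c(0, 0, 20, 0))
  set.seed(7)
  scores <- rbind(
    sweep(matrix(rnorm(25 * 4, sd = 0.2), 25, 4), 2, centroids[1, ], "+"),
    sweep(matrix(rnorm(30 * 4, sd = 0.2), 30, 4), 2, centroids[2, ], "+"),
    sweep(matrix(rnorm(25 * 4, sd = 0.2), 25, 4), 2, centroids[3, ], "+"),
    sweep(matrix(rnorm(10 * 4, sd = 0.2), 10, 4), 2, centroids[4, ], "+"))
  labels <- c(rep(1, 25), rep(4, 30), rep(2, 25), rep(4, 10))
  m <- match_centroids(centroids, scores, labels)
  expect_equal(nrow(m$centroids), 3)
  expect_setequal(m$labels, c(1, 2, 4))
  expect_equal(m$n_vote_segments[m$labels == 4], 30)
  expect_equal(m$centroids[m$labels == 4, ], centroids[2, ])
})

test_that("empty regions drop their centroid; an all-empty vote is fatal", {
  centroids <- rbind(c(0, 0), c(100, 100))
  scores <- matrix(rnorm(20, sd = 0.1), 10, 2)
  m <- match_centroids(centroids, scores, rep(2, 10))
  expect_equal(nrow(m$centroids), 1)
  expect_equal(m$labels, 2)
  expect_error(match_centroids(centroids[0, , drop = FALSE], scores,
                               rep(1, 10)))
})

test_that("prototype labels come from votes, not from cluster indices", {
  set.seed(9)
  means <- diag(4) * 8
  scores <- do.call(rbind, lapply(1:4, function(i)
    sweep(matrix(rnorm(25 * 4, sd = 0.3), 25, 4), 2, means[i, ], "+")))
  labels <- rep(c(3, 1, 4, 2), each = 25)
  for (perm in list(1:4, c(2, 4, 1, 3), 4:1)) {
    m <- match_centroids(means[perm, ], scores, labels)
    got <- m$labels[order(apply(m$centroids, 1, which.max))]
    expect_equal(got, c(3, 1, 4, 2))
  }
})

test_that("model-driven prototyping finds four labeled states reproducibly", {
  run <- selfclass_run(1)
  proto <- run$prototypes
  expect_equal(sort(proto$labels), 1:4)
  # with all four centroids kept the Voronoi vote partitions all 400
  # generating segments, nearly all backing their region's label
  expect_equal(sum(proto$region_sizes), 400)
  expect_gte(sum(proto$n_vote_segments), 0.95 * 400)
  # deterministic rebuild
  fm <- segment_features(run$segments, "model")
  proto2 <- fit_prototypes(fm, seed = 1)
  expect_equal(proto2$centroids, proto$centroids)
  expect_equal(proto2$labels, proto$labels)
  # self-consistency: nearly all generating segments sit in the right cell
  pred <- run$predictions
  expect_gte(mean(pred$predicted_label == segment_labels(run$segments)),
             0.95)
})

test_that("prototype sets survive a JSON round trip", {
  proto <- selfclass_run(1)$prototypes
  path <- withr::local_tempfile(fileext = ".json")
  write_prototypes(proto, path)
  back <- read_prototypes(path)
  expect_equal(back$centroids, proto$centroids, tolerance = 1e-12)
  expect_equal(back$labels, proto$labels)
  expect_equal(back$projection$coefficients, proto$projection$coefficients,
               tolerance = 1e-12, ignore_attr = TRUE)
  fm <- segment_features(small_type_set(), "probe")
  expect_equal(predict(back, fm)$predicted_label,
               predict(proto, fm)$predicted_label)
})
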
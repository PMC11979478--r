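test_that("k-means recovers enumerable solutions on hand instances", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  m <- fit_kmeans(x, 2, seed = 1)
  expect_equal(sort(m$centroids[, 1]), c(0.5, 10.5))
  expect_equal(m$inertia, 1.0)
  # k = n distinct points: zero inertia
  expect_equal(fit_kmeans(x, 4, seed = 1)$inertia, 0)
  # k = 1: coordinate-wise mean
  expect_equal(fit_kmeans(x, 1)$centroids[1, 1], mean(x))
  expect_error(fit_kmeans(matrix(c(1, 1, 2), ncol = 1), 3), "distinct")
})

test_that("assignment is nearest-centroid with lowest-index tie-breaking", {
  m <- structure(list(k = 2L, centroids = rbind(c(0, 0), c(4, 0)),
                      inertia = 0, labels = c(1L, 2L), seed = 1L),
                 class = "kmeans_model")
  expect_equal(assign_clusters(m, rbind(c(4, 0))), 2L)      # exactly at mu_2
  expect_equal(assign_clusters(m, rbind(c(2, 0))), 1L)      # equidistant -> 1
  expect_error(assign_clusters(m, matrix(0, 1, 3)), "dimension")
  # oracle comparison on random instances
  for (seed in 1:5) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(60), 20, 3)
      ctr <- matrix(rnorm(12), 4, 3)
    })
    m4 <- structure(list(k = 4L, centroids = ctr), class = "kmeans_model")
    expect_equal(assign_clusters(m4, x), oracle_assign(ctr, x))
  }
})

test_that("prediction strength matches the pair-counting oracle fold by fold", {
  # 40-point fixture from two overlapping Gaussians, scored at k = 3
  blobs <- make_blobs(20, rbind(c(0, 0), c(1.5, 0)), sd = 0.8, seed = 7)
  x <- blobs$x
  ps <- prediction_strength(x, ks = 1:3, n_folds = 4, seed = 11)
  folds <- withr::with_seed(hfsubtype:::derive_seed(11, "ps-folds"),
                            sample(rep_len(1:4, nrow(x))))
  for (fold in 1:4) {
    test_idx <- which(folds == fold); train_idx <- which(folds != fold)
    for (k in 2:3) {
      m_train <- fit_kmeans(x[train_idx, ], k,
                            seed = hfsubtype:::derive_seed(11, "ps", fold, k, "train"))
      m_test <- fit_kmeans(x[test_idx, ], k,
                           seed = hfsubtype:::derive_seed(11, "ps", fold, k, "test"))
      expected <- oracle_ps_fold(x[test_idx, ], m_test$labels, m_train$centroids)
      got <- ps$ps[ps$k == k & ps$fold == fold]
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }
  # ps(1) = 1 by definition, in every fold
  expect_true(all(ps$ps[ps$k == 1] == 1))
})

test_that("two well-separated point masses give prediction strength 1 at k = 2", {
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
             matrix(rnorm(40, 50, 0.05), 20, 2))
  ps <- prediction_strength(x, ks = 1:2, n_folds = 5, seed = 3)
  expect_equal(ps_means(ps)$mean_ps, c(1, 1))
})

test_that("the selection rule returns the largest qualifying k", {
  fake_curve <- function(means) {
    curve <- tibble::tibble(k = means$k, fold = 1L, ps = means$mean_ps)
    structure(curve, class = c("ps_curve", class(curve)), means = means)
  }
  c1 <- fake_curve(tibble::tibble(k = 1:4, mean_ps = c(1, 0.95, 0.9, 0.6)))
  expect_equal(select_optimal_k(c1, 0.8), 3L)
  c2 <- fake_curve(tibble::tibble(k = 1:4, mean_ps = c(1, 0.5, 0.4, 0.3)))
  expect_warning(k <- select_optimal_k(c2, 0.8), "k = 1")
  expect_equal(k, 1L)
  expect_error(select_optimal_k(fake_curve(tibble::tibble(k = integer(),
                                                          mean_ps = numeric()))),
               "empty")
})

test_that("single-Gaussian data show decaying prediction strength", {
  x <- withr::with_seed(13, matrix(rnorm(300), 150, 2))
  ps <- ps_means(prediction_strength(x, ks = 1:4, n_folds = 5, seed = 13))
  expect_equal(ps$mean_ps[1], 1)
  expect_lt(ps$mean_ps[4], 0.7)   # substantially below the k = 1 anchor
})

test_that("input-order permutations do not change the curve (same seed)", {
  blobs <- make_blobs(15, rbind(c(0, 0), c(6, 0)), seed = 17)
  ps1 <- ps_means(prediction_strength(blobs$x, ks = 1:2, seed = 5))
  perm <- withr::with_seed(1, sample(nrow(blobs$x)))
  ps2 <- ps_means(prediction_strength(blobs$x[perm, ], ks = 1:2, seed = 5))
  expect_equal(ps1$mean_ps, ps2$mean_ps, tolerance = 1e-9)
})

test_that("fold and k guards reject impossible requests", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(prediction_strength(x, ks = 1:2, n_folds = 1), "n_folds")
  expect_error(prediction_strength(x, ks = 1:10, n_folds = 5), "fold")
})
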
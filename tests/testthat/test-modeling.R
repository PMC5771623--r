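test_that("anova_kernel matches its closed form", {
  ks <- kernel_spec(gamma = 1, d = 1L)
  expect_equal(anova_kernel(0, 1, ks), exp(-1))
  expect_equal(anova_kernel(c(1, 2, 3), c(1, 2, 3), kernel_spec(0.5, 2L)), 9)
  expect_error(anova_kernel(1:2, 1:3, ks), "equal length")

  # symmetry on random pairs
  withr::with_seed(31, {
    for (i in 1:50) {
      x <- rnorm(4); y <- rnorm(4)
      expect_equal(anova_kernel(x, y, kernel_spec(0.3, 3L)),
                   anova_kernel(y, x, kernel_spec(0.3, 3L)))
    }
  })
})

test_that("gram_matrix is symmetric, PSD for d = 1, and consistent", {
  ks <- kernel_spec(0.7, 1L)
  withr::with_seed(17, {
    for (rep in 1:5) {
      X <- matrix(rnorm(30 * 4), 30)
      K <- gram_matrix(X, ks)
      expect_equal(K, t(K))
      expect_equal(unname(diag(K)), rep(4, 30))
      expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-9)
    }
  })
  # identical rows give the constant matrix p^d
  Xc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_true(all(gram_matrix(Xc, kernel_spec(1, 2L)) == 9))
  # the 2x2 case equals pairwise kernel calls
  X2 <- matrix(c(0, 1, 2, -1), 2)
  K2 <- gram_matrix(X2, ks)
  expect_equal(K2[1, 2], anova_kernel(X2[1, ], X2[2, ], ks))
})

test_that("fit_predict_svr interpolates, degenerates and learns", {
  x <- matrix(seq(0, 1, length.out = 20))
  y <- 2 * x[, 1]
  # interpolation limit: large C, zero tube
  p <- fit_predict_svr(x, y, x, svr_config(C = 1e6, epsilon = 0))
  expect_lt(max(abs(p - y)), 0.01)

  # constant labels -> constant predictions with warning
  expect_warning(pc <- fit_predict_svr(x, rep(3, 20), x), "degenerate")
  expect_equal(unname(as.numeric(pc)), rep(3, 20))

  # noise-free linear relation, default config, held-out points
  xte <- matrix(withr::with_seed(4, runif(40)))
  pte <- fit_predict_svr(x, y, xte)
  expect_lt(sqrt(mean((pte - 2 * xte[, 1])^2)), 0.1 * sd(y))

  expect_error(fit_predict_svr(x[1, , drop = FALSE], y[1], x), ">= 2")
  expect_error(fit_predict_svr(x, y, matrix(1, 2, 2)), "columns")
  xna <- x; xna[3, 1] <- NA
  expect_error(fit_predict_svr(xna, y, x), "missing values")
})

test_that("kfold_split is balanced, covering and seeded", {
  f8 <- kfold_split(8, 4, seed = 2)
  expect_equal(sort(unique(f8)), 1:4)
  expect_true(all(table(f8) == 2))

  f10 <- kfold_split(10, 4, seed = 2)
  expect_equal(sort(as.integer(table(f10))), c(2, 2, 3, 3))
  expect_identical(kfold_split(10, 4, seed = 2), f10)
  expect_false(identical(kfold_split(10, 4, seed = 3), f10))
  expect_error(kfold_split(3, 4), "at least k")
})

test_that("regression_metrics implements the metric triple", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$r2, m$rmse, m$re), c(1, 0, 0))

  m2 <- regression_metrics(c(2, 4), c(1, 3))
  expect_equal(m2$rmse, 1.0)
  expect_equal(m2$re, 50.0)

  expect_warning(m3 <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(m3$r2, 0)
  expect_true(is.finite(m3$rmse))

  expect_error(regression_metrics(1:3, 1:4), "equal length")
  expect_error(regression_metrics(c(1, 2), c(-3, 1)), "non-positive")

  # RE invariant under common positive rescaling; RMSE scales linearly
  p <- c(2.2, 3.1, 1.4); o <- c(2.0, 3.0, 1.6)
  a <- regression_metrics(p, o)
  b <- regression_metrics(10 * p, 10 * o)
  expect_equal(b$re, a$re)
  expect_equal(b$rmse, 10 * a$rmse)
})

test_that("pooled CV predicts each labeled sample exactly once with paired folds", {
  ds <- small_dataset(n = 24, seed = 6)
  ft <- assemble_features(ds)
  labels <- sample_labels(ds)
  res <- run_experiment(features = ft, labels = labels, seed = 9)
  expect_named(res, c("vi4", "fluor2", "combined"))
  for (r in res) {
    expect_equal(r$n, 24)
    expect_length(r$predictions, 24)
  }
  expect_identical(res$vi4$fold_assignments, res$combined$fold_assignments)
  expect_identical(res$vi4$fold_assignments, res$fluor2$fold_assignments)

  # pooled metrics equal metrics on concatenated per-fold vectors
  r <- res$vi4
  folds <- r$fold_assignments
  ord <- order(folds)
  m_pooled <- suppressWarnings(regression_metrics(r$predictions, r$observed))
  m_cat <- suppressWarnings(
    regression_metrics(r$predictions[ord], r$observed[ord]))
  expect_equal(m_cat$rmse, m_pooled$rmse)
  expect_equal(m_cat$r2, m_pooled$r2)

  expect_error(run_experiment(features = ft, labels = labels,
                              feature_sets = list(bad = "NOPE")),
               "unknown feature")
})

test_that("rank_single_features is deterministic and duplicate-consistent", {
  ds <- small_dataset(n = 24, seed = 13)
  fl <- compute_fluorescence_params(ds)
  dup <- cbind(fl$values, DUP = fl$values[, "F685_F460"])
  ft <- feature_table(dup, fl$sample_ids)
  rk <- rank_single_features(ft, sample_labels(ds), seed = 3)
  expect_equal(rk$r2[rk$feature == "DUP"], rk$r2[rk$feature == "F685_F460"])
  rk2 <- rank_single_features(ft, sample_labels(ds), seed = 3)
  expect_identical(rk, rk2)
  expect_false(is.unsorted(rev(rk$r2)))

  # constant columns are excluded with a warning
  bad <- cbind(fl$values, CONST = 1)
  expect_warning(
    rk3 <- rank_single_features(feature_table(bad, fl$sample_ids),
                                sample_labels(ds), seed = 3),
    "excluded")
  expect_false("CONST" %in% rk3$feature)
})

test_that("an uninformative modality does not hurt the combined model much", {
  # reflectance decoupled: combined should track fluor2 within 0.05 R2
  diffs <- vapply(1:6, function(s) {
    ds <- generate_dataset(synthetic_config(
      n_samples = 120, seed = 400 + s, coupling_reflectance = 0))
    res <- run_experiment(samples = ds, seed = s)
    res$fluor2$r2 - res$combined$r2
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})
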
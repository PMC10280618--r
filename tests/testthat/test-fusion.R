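test_that("random-forest selection keeps k columns and finds the signal", {
  ft <- planted_feature_table(seed = 2, n = 40, n_informative = 20,
                              n_junk = 10)
  X <- as.matrix(ft[, -(1:3)])
  sel <- select_features_rf(X, ft$glucose_ref, k = 25, seed = 7)
  expect_length(sel, 25L)
  expect_true(all(sel %in% seq_len(ncol(X))))
  expect_identical(sel, select_features_rf(X, ft$glucose_ref, k = 25,
                                           seed = 7))
  expect_error(select_features_rf(X[, 1:10], ft$glucose_ref, k = 25), "25")

  # a column equal to the target must be picked almost always
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    g <- runif(30, 4, 12)
    X <- cbind(g, matrix(rnorm(30 * 9), ncol = 9))
    1 %in% select_features_rf(X, g, k = 3, seed = s)
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("base regressors fit, predict and respect the seed", {
  ft <- planted_feature_table(seed = 5)
  X <- as.matrix(ft[, 4:13])
  g <- ft$glucose_ref
  for (kind in c("rf", "svr", "gpr")) {
    m <- train_base_model(X, g, kind, seed = 3)
    p <- predict(m, X)
    expect_length(p, nrow(X))
    expect_true(all(is.finite(p)))
  }
  m1 <- train_base_model(X, g, "rf", seed = 3)
  m2 <- train_base_model(X, g, "rf", seed = 3)
  expect_equal(predict(m1, X), predict(m2, X))
  # the forest reproduces its own noiseless training targets well
  expect_lt(mean(abs(predict(m1, X) - g)), stats::sd(g))

  const <- train_base_model(X, rep(5.5, nrow(X)), "rf")
  expect_equal(predict(const, X[1:3, ]), rep(5.5, 3), tolerance = 1e-6)
})

test_that("the fusion split is 2/3 + 1/3, disjoint and exhaustive", {
  sp <- split_for_fusion(60, seed = 4)
  expect_length(sp$new_train, 40L)
  expect_length(sp$validation, 20L)
  expect_identical(sort(c(sp$new_train, sp$validation)), 1:60)
  expect_error(split_for_fusion(5), "at least 9")

  # 80 measurements -> 75% train (60) -> 2/3 of that (40) = 50% of all
  overall <- tibble::tibble(subject_id = 1, measurement_id = 1:80,
                            glucose_ref = runif(80, 4, 10))
  tr <- split_train_test(overall, 0.75, seed = 1)$train
  expect_equal(nrow(tr), 60L)
  sp2 <- split_for_fusion(nrow(tr), seed = 1)
  expect_equal(length(sp2$new_train) / 80, 0.5)
  expect_equal(length(sp2$validation) / 80, 0.25)
})

test_that("region partitioning follows the accumulate-probability walk", {
  cfg <- fusion_config(epsilon = 0.6, min_region_points = 3)
  g <- seq(4, 9.5, by = 0.5)              # 12 ascending values

  # single dominant winner: every region carries that method, so the
  # partition is equivalent to a single region over the whole axis
  p0 <- partition_regions(g, rep("L1", 12), cfg)
  expect_identical(unique(p0$region_methods), "L1")

  # hand-traced sequence: resets after points 3, 6, 9 and 12
  winners <- c("L1", "L1", "L1", "L1", "L2", "L2",
               "L2", "L2", "Linf", "Linf", "Linf", "Linf")
  p1 <- partition_regions(g, winners, cfg)
  expect_identical(p1$region_methods, c("L1", "L2", "L2", "Linf"))
  expect_equal(p1$boundaries,
               c(mean(g[3:4]), mean(g[6:7]), mean(g[9:10])))

  # epsilon -> 1: the threshold never fires on mixed winners, everything
  # is one region labelled by plurality
  mixed <- rep(c("L1", "L2"), 6)
  p2 <- partition_regions(g, mixed, fusion_config(epsilon = 0.999))
  expect_length(p2$region_methods, 1L)
  expect_length(p2$boundaries, 0L)
  expect_identical(p2$region_methods, "L1")   # tie -> priority order
})

test_that("fused prediction applies the region lookup rule", {
  # two regions split at 7.0; estimates straddle the boundary
  fm <- constant_fusion_model(list(5.0, 6.0, 7.3), boundaries = 7.0,
                              region_methods = c("L1", "Linf"))
  x <- matrix(0, 1, 2)
  expect_equal(predict(fm, x), 5.0)       # locator 6.1 -> first region -> L1

  # identical estimates are returned unchanged whatever the regions
  fm2 <- constant_fusion_model(list(6.4, 6.4, 6.4), boundaries = 7.0,
                               region_methods = c("L1", "Linf"))
  expect_equal(predict(fm2, x), 6.4)

  # single-region dominance: output always equals that model's estimate
  fm3 <- constant_fusion_model(list(5.0, 6.0, 7.3), boundaries = numeric(0),
                               region_methods = "L2")
  expect_equal(predict(fm3, x), 6.0)
})

test_that("building a fusion model yields three forests and valid regions", {
  ft <- planted_feature_table(seed = 12, n = 36)
  X <- as.matrix(ft[, -(1:3)])
  g <- ft$glucose_ref
  cfg <- fusion_config(seed = 9, n_selected_features = 20)
  fm <- suppressWarnings(build_fusion_model(X, g, cfg))
  expect_s3_class(fm, "fusion_model")
  expect_identical(sort(names(fm$models)), c("L1", "L2", "Linf"))
  expect_gte(length(fm$region_methods), 1L)
  expect_length(fm$boundaries, length(fm$region_methods) - 1L)
  expect_true(all(fm$region_methods %in% c("L1", "L2", "Linf")))

  # winners attain the row minimum of the three error vectors
  v <- fm$validation
  e <- cbind(L1 = v$e1, L2 = v$e2, Linf = v$einf)
  for (i in seq_len(nrow(e))) {
    expect_equal(unname(e[i, v$winner[i]]), unname(min(e[i, ])))
  }

  # determinism under the same config seed
  fm2 <- suppressWarnings(build_fusion_model(X, g, cfg))
  expect_identical(fm$boundaries, fm2$boundaries)
  expect_identical(fm$region_methods, fm2$region_methods)

  # every locator maps to exactly one region
  est <- predict(fm, X)
  expect_true(all(is.finite(est)))
  td <- tidy(fm)
  expect_equal(nrow(td), length(fm$region_methods))
  expect_equal(td$lower[1], -Inf)
  expect_equal(td$upper[nrow(td)], Inf)
})
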
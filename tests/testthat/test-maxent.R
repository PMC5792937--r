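test_that("auto feature classes follow the presence-count thresholds", {
  st <- toy_stack(n = 10, layers = 1, seed = 5)
  classes_for <- function(np)
    unique(build_features(st, n_presences = np)$descriptors$class)
  expect_equal(classes_for(5), "linear")
  expect_setequal(classes_for(10), c("linear", "quadratic"))
  expect_setequal(classes_for(15), c("linear", "quadratic", "hinge"))
  st2 <- toy_stack(n = 10, layers = 2, seed = 5)
  expect_setequal(unique(build_features(st2, 80)$descriptors$class),
                  c("linear", "quadratic", "hinge", "threshold", "product"))
})

test_that("categorical layers expand to one indicator per observed code", {
  cat3 <- raster_grid(matrix(rep(1:3, length.out = 100), 10, 10),
                      name = "soil", kind = "categorical")
  st <- env_stack(list(cat3))
  fm <- build_features(st, 5)
  expect_equal(sum(fm$descriptors$class == "categorical"), 3)
  expect_true(all(fm$X %in% c(0, 1)))

  cat1 <- raster_grid(matrix(2, 10, 10), name = "soil", kind = "categorical")
  cont <- raster_grid(matrix(runif(100), 10, 10), name = "e")
  expect_warning(fm1 <- build_features(env_stack(list(cont, cat1)), 5),
                 "single observed category")
  expect_false("categorical" %in% fm1$descriptors$class)
})

test_that("explicit feature mode counts features per class and layer", {
  st <- toy_stack(n = 10, layers = 2, seed = 6)
  fm <- build_features(st, 5, mode = "explicit",
                       classes = c("linear", "quadratic"))
  expect_equal(ncol(fm$X), 4)
  expect_true(all(fm$X >= 0 & fm$X <= 1))
})

test_that("the two-cell model recovers the closed-form weight and map", {
  fm <- two_cell_features()
  # presence sample mean 0.75 on env values {0, 1}: lambda = ln 3
  fit <- fit_maxent(fm, c(1, 2, 2, 2), reg_multiplier = 0, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_equal(fit$lambda, log(3), tolerance = 1e-4)
  map <- predict_raw(fit, fm)
  expect_equal(map$p, c(0.25, 0.75), tolerance = 1e-6)
})

test_that("uniform presence usage gives a near-uniform map", {
  st <- toy_stack(n = 6, layers = 2, seed = 7)
  fm <- build_features(st, 36, mode = "explicit", classes = "linear")
  fit <- fit_maxent(fm, fm$cell_ids, reg_multiplier = 0, tolerance = 1e-9)
  map <- predict_raw(fit, fm)
  expect_equal(max(abs(map$p - 1 / 36)), 0, tolerance = 1e-6)
})

test_that("unpenalized linear fits match presence feature means (moment matching)", {
  for (seed in 1:4) {
    st <- toy_stack(n = 8, layers = 2, seed = seed)
    fm <- build_features(st, 6, mode = "explicit", classes = "linear")
    set.seed(seed)
    cells <- sample(fm$cell_ids, 6)
    fit <- fit_maxent(fm, cells, reg_multiplier = 0)
    map <- predict_raw(fit, fm)
    e_model <- drop(crossprod(fm$X, map$p))
    expect_lt(max(abs(e_model - fit$presence_means)), 1e-3)
  }
})

test_that("the fitted optimum matches a dense grid-search oracle on a tiny domain", {
  # 4-cell domain, one linear feature: profile the exact penalized
  # objective over a lambda grid and compare
  st <- env_stack(list(raster_grid(matrix(c(0.1, 0.4, 0.7, 1.0), 2, 2),
                                   name = "e")))
  fm <- build_features(st, 3, mode = "explicit", classes = "linear")
  cells <- c(fm$cell_ids[3], fm$cell_ids[4], fm$cell_ids[4])
  fit <- fit_maxent(fm, cells, reg_multiplier = 0, tolerance = 1e-9)
  obj <- function(l) {
    eta <- fm$X * l
    -3 * mean(fm$X[match(cells, fm$cell_ids)]) * l +
      3 * log(sum(exp(eta)))
  }
  grid <- seq(-20, 20, by = 0.001)
  l_star <- grid[which.min(vapply(grid, obj, 1))]
  expect_equal(fit$lambda, l_star, tolerance = 2e-3)
})

test_that("the penalized objective is non-increasing across accepted iterations", {
  st <- toy_stack(n = 8, layers = 3, seed = 11)
  fm <- build_features(st, 12, mode = "explicit",
                       classes = c("linear", "quadratic"))
  set.seed(11)
  fit <- fit_maxent(fm, sample(fm$cell_ids, 12), reg_multiplier = 1)
  expect_true(all(diff(fit$trace) <= 1e-10))
})

test_that("raising the regularization multiplier shrinks weights monotonically", {
  st <- toy_stack(n = 8, layers = 1, seed = 12)
  fm <- build_features(st, 8, mode = "explicit", classes = "linear")
  set.seed(12)
  cells <- sample(fm$cell_ids, 8)
  lam <- vapply(c(0, 0.5, 1, 2, 4), function(r)
    abs(fit_maxent(fm, cells, reg_multiplier = r, tolerance = 1e-8)$lambda),
    numeric(1))
  expect_true(all(diff(lam) <= 1e-8))
})

test_that("prediction is invariant to a constant shift of a feature", {
  st <- toy_stack(n = 8, layers = 1, seed = 13)
  fm <- build_features(st, 8, mode = "explicit", classes = "linear")
  set.seed(13)
  cells <- sample(fm$cell_ids, 8)
  fit <- fit_maxent(fm, cells, reg_multiplier = 0, tolerance = 1e-9)
  map1 <- predict_raw(fit, fm)
  fm2 <- fm
  fm2$X <- fm$X + 0.37           # shift absorbed by the normalizer
  fit2 <- fit
  map2 <- predict_raw(fit2, fm2)
  expect_equal(map2$p, map1$p, tolerance = 1e-6)
})

test_that("complete separation under zero penalty is capped and flagged", {
  # presences all in the single cell with the extreme value
  st <- env_stack(list(raster_grid(matrix(c(0, 0, 0, 1), 2, 2), name = "e")))
  fm <- build_features(st, 3, mode = "explicit", classes = "linear")
  top <- fm$cell_ids[which.max(fm$X[, 1])]
  expect_warning(fit <- fit_maxent(fm, rep(top, 3), reg_multiplier = 0),
                 "cap")
  expect_false(fit$converged)
  expect_lte(max(abs(fit$lambda)), 50)
})

test_that("presences outside the valid domain are rejected", {
  v <- matrix(runif(16), 4, 4); v[1, 1] <- NA
  st <- env_stack(list(raster_grid(v, name = "e")))
  fm <- build_features(st, 2, mode = "explicit", classes = "linear")
  expect_error(fit_maxent(fm, cell_id(1L, 1L, 4L)), "outside the valid domain")
})

test_that("rank-based AUC equals the brute-force pairwise comparison", {
  expect_equal(compute_auc(c(0.9, 0.4), c(0.5, 0.1, 0.3)), 5 / 6)
  expect_equal(compute_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(compute_auc(0.5, 0.5), 0.5)
  set.seed(42)
  for (i in 1:100) {
    pres <- round(runif(sample(1:8, 1)), 1)   # rounding forces ties
    bg <- round(runif(sample(1:8, 1)), 1)
    expect_equal(compute_auc(pres, bg), auc_brute(pres, bg))
  }
  expect_error(compute_auc(numeric(), 1), "non-empty")
})

test_that("suitability maps are normalized probability surfaces", {
  st <- toy_stack(n = 8, layers = 2, seed = 14)
  fm <- build_features(st, 10, mode = "explicit",
                       classes = c("linear", "quadratic"))
  set.seed(14)
  fit <- fit_maxent(fm, sample(fm$cell_ids, 10))
  map <- predict_raw(fit, fm)
  expect_true(all(map$p >= 0))
  expect_equal(sum(map$p), 1, tolerance = 1e-9)
  g <- suitability_grid(map)
  expect_equal(sum(g$values, na.rm = TRUE), 1, tolerance = 1e-9)
  # descriptor mismatch is an error
  fm_other <- build_features(st, 5, mode = "explicit", classes = "linear")
  expect_error(predict_raw(fit, fm_other), "descriptors")
})

test_that("model serialization writes descriptors, penalties and weights", {
  fm <- two_cell_features()
  fit <- fit_maxent(fm, c(1, 2, 2, 2), reg_multiplier = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_maxent_model(fit, path)
  txt <- readLines(path)
  expect_true(any(grepl("^# n_presences\t4$", txt)))
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$lambda, fit$lambda, tolerance = 1e-10)
})
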
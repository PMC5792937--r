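test_that("synthetic stacks are seeded, bounded, and spatially autocorrelated", {
  a <- make_env_stack(16, 16, 2, 1, smoothness = 3, seed = 1)
  b <- make_env_stack(16, 16, 2, 1, smoothness = 3, seed = 1)
  expect_equal(a$layers[["env01"]]$values, b$layers[["env01"]]$values)
  expect_equal(a$kinds, c(env01 = "continuous", env02 = "continuous",
                          soil01 = "categorical"))
  v <- a$layers[["env01"]]$values
  expect_gte(min(v), 0); expect_lte(max(v), 1)
  expect_gte(length(unique(as.vector(a$layers[["soil01"]]$values))), 2)

  # lag-1 spatial autocorrelation of a smooth field beats shuffled values
  lag1 <- function(m) stats::cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  set.seed(2)
  shuffled <- matrix(sample(v), nrow(v))
  expect_gt(lag1(v), lag1(shuffled) + 0.3)

  # smoothness -> large: variance collapses
  flat <- make_env_stack(16, 16, 1, 0, smoothness = 50, seed = 3)
  raw <- make_env_stack(16, 16, 1, 0, smoothness = 0, seed = 3)
  # both are rescaled to [0,1]; compare roughness instead of raw variance
  expect_gt(lag1(flat$layers[[1]]$values), lag1(raw$layers[[1]]$values))
  expect_error(make_env_stack(4, 4), "8 x 8")
})

test_that("simulated trees are pure-birth, unit depth, ultrametric", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(sort(tr$tip.label), c("sp01", "sp02"))
  expect_equal(tr$edge.length, c(1, 1))
  for (n in c(5, 16)) {
    tr <- simulate_tree(n, seed = n)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_equal(depths, rep(1, n), tolerance = 1e-9)
    expect_true(attr(tr, "ultrametric"))
  }
  expect_identical(ape::write.tree(simulate_tree(8, seed = 4)),
                   ape::write.tree(simulate_tree(8, seed = 4)))
})

test_that("Brownian niche evolution matches its theoretical moments", {
  cherry <- read_tree("(sp01:1,sp02:1);")
  # sigma2 = 0: everything sits at the root optimum
  o0 <- evolve_niches(cherry, 0, c(0.5, 0.2), seed = 1)
  expect_equal(unname(o0), matrix(c(0.5, 0.5, 0.2, 0.2), 2))
  # tip variance over replicates approximates sigma2 * depth
  vals <- vapply(1:1000, function(s)
    evolve_niches(cherry, 0.3, 0, seed = s)[1, 1], numeric(1))
  expect_lt(abs(stats::var(vals) - 0.3), 0.05)   # ~3.7 SE of the estimator
})

test_that("sister tips have more similar optima than distant tips", {
  tr <- read_tree("((a:0.1,b:0.1):0.9,(c:0.1,d:0.1):0.9);")
  tr$tip.label <- c("a", "b", "c", "d")
  d_sis <- d_far <- numeric(200)
  for (s in 1:200) {
    o <- evolve_niches(tr, 0.2, 0, seed = 500 + s)
    d_sis[s] <- abs(o["a", 1] - o["b", 1])
    d_far[s] <- abs(o["a", 1] - o["c", 1])
  }
  expect_lt(mean(d_sis), mean(d_far))
})

test_that("occurrence sampling concentrates near the optimum and is seeded", {
  st <- make_env_stack(24, 24, 2, 0, smoothness = 4, seed = 9)
  opt <- matrix(c(0.9, 0.9), 1, dimnames = list("spX", NULL))
  occ1 <- sample_occurrences(st, opt, tau = 0.05, n_per_species = 25, seed = 3)
  occ2 <- sample_occurrences(st, opt, tau = 0.05, n_per_species = 25, seed = 3)
  expect_identical(occ1, occ2)
  expect_equal(nrow(occ1), 25)
  expect_false(any(duplicated(occ1$cell)))  # without replacement

  E <- env_values(st)
  at_cells <- E[match(occ1$cell, attr(E, "cell_ids")), ]
  dom_gap <- sqrt(sum((colMeans(E) - c(0.9, 0.9))^2))
  occ_gap <- sqrt(sum((colMeans(at_cells) - c(0.9, 0.9))^2))
  expect_lt(occ_gap, dom_gap)              # closer to the optimum than average

  # tau -> infinity approaches uniform sampling: mean near the domain mean
  occ_u <- sample_occurrences(st, opt, tau = 1e6, n_per_species = 200, seed = 4)
  at_u <- E[match(occ_u$cell, attr(E, "cell_ids")), ]
  expect_lt(sqrt(sum((colMeans(at_u) - colMeans(E))^2)), 0.08)
  expect_error(sample_occurrences(st, opt, 0.1, 10000), "exceeds")
})

test_that("background pools honour union and uniform modes", {
  w <- simulate_world(n_rows = 16, n_cols = 16, n_continuous = 2,
                      n_categorical = 0, n_tips = 3, n_per_species = 5,
                      seed = 21)
  union_pool <- make_background_pool(w, "union")
  expect_setequal(union_pool$cells, unique(w$occurrences$cell))
  uni <- make_background_pool(w, "uniform", n_pool = 30, seed = 1)
  expect_equal(length(uni$cells), 30)
  expect_false(any(duplicated(uni$cells)))
  all_cells <- make_background_pool(w, "uniform",
                                    n_pool = length(valid_cells(w$env)),
                                    seed = 1)
  expect_setequal(all_cells$cells, valid_cells(w$env))
})

test_that("whole worlds are reproducible from the master seed", {
  w1 <- simulate_world(n_rows = 16, n_cols = 16, n_tips = 4,
                       n_per_species = 5, seed = 77)
  w2 <- simulate_world(n_rows = 16, n_cols = 16, n_tips = 4,
                       n_per_species = 5, seed = 77)
  expect_equal(w1$occurrences, w2$occurrences)
  expect_equal(w1$optima, w2$optima)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_setequal(w1$pool$cells, w2$pool$cells)
  expect_true(all(w1$occurrences$cell %in% valid_cells(w1$env)))
  expect_setequal(rownames(w1$optima), w1$tree$tip.label)
})

test_that("worlds serialize to plain-text files and read back", {
  w <- simulate_world(n_rows = 12, n_cols = 12, n_continuous = 2,
                      n_categorical = 1, n_tips = 3, n_per_species = 4,
                      seed = 31)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  st <- read_env_stack(file.path(dir, c("env01.asc", "env02.asc", "soil01.asc")),
                       kinds = c("continuous", "continuous", "categorical"))
  expect_equal(st$layers[["env01"]]$values,
               w$env$layers[["env01"]]$values, tolerance = 1e-9)
  occ <- read_occurrences(file.path(dir, "occurrences.csv"))
  expect_equal(nrow(occ), nrow(w$occurrences))
  tr <- read_tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, w$tree$tip.label)
  prm <- yaml::read_yaml(file.path(dir, "params.yml"))
  expect_equal(prm$seed, 31)
})
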
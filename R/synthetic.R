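# Synthetic worlds with known truth: smooth environmental fields, a
# pure-birth chronogram, niche optima evolving by Brownian motion on it,
# occurrences sampled by Gaussian suitability, and a target-group pool.
# Every generator is seeded; the same seed reproduces the same world.

# Gaussian blur with edge renormalization (separable kernel)
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  smooth1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- matrix(0, n, ncol(m))
    for (off in seq(-r, r)) {
      w <- k[off + r + 1]
      src <- pmin(pmax(seq_len(n) + off, 1L), n)  # reflect-ish clamp
      out <- out + w * m[src, , drop = FALSE]
      wsum <- wsum + w
    }
    out / wsum
  }
  t(smooth1(t(smooth1(mat))))
}

#' Generate a synthetic environmental stack
#'
#' Continuous layers are Gaussian-smoothed white-noise fields rescaled to
#' \[0, 1\] (spatially autocorrelated, like interpolated climate surfaces);
#' categorical layers are quantile-sliced smooth fields, giving contiguous
#' patches of integer codes.
#'
#' @param n_rows,n_cols grid dimensions (>= 8 each).
#' @param n_continuous,n_categorical layer counts.
#' @param smoothness Gaussian blur standard deviation in cells; larger =
#'   smoother (variance of the rescaled field shrinks toward 0 as it grows).
#' @param n_codes number of categories per categorical layer.
#' @param seed RNG seed.
#' @return an [env_stack()].
#' @export
make_env_stack <- function(n_rows = 64, n_cols = 64, n_continuous = 4,
                           n_categorical = 1, smoothness = 6, n_codes = 4,
                           seed = NULL) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  if (n_continuous + n_categorical < 1) stop("need at least one layer")
  if (!is.null(seed)) set.seed(seed)
  layers <- list()
  field <- function() {
    f <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows), smoothness)
    if (max(f) > min(f)) (f - min(f)) / (max(f) - min(f)) else f * 0 + 0.5
  }
  for (i in seq_len(n_continuous))
    layers[[length(layers) + 1L]] <-
      raster_grid(field(), name = sprintf("env%02d", i))
  for (i in seq_len(n_categorical)) {
    f <- field()
    br <- stats::quantile(f, probs = seq(0, 1, length.out = n_codes + 1))
    codes <- matrix(as.numeric(cut(f, unique(br), include.lowest = TRUE)),
                    n_rows, n_cols)
    layers[[length(layers) + 1L]] <-
      raster_grid(codes, name = sprintf("soil%02d", i), kind = "categorical")
  }
  env_stack(layers)
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree rescaled to unit depth; all root-to-tip distances
#' equal 1.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed.
#' @return a `phylo` object with tips `sp01, sp02, ...` and attribute
#'   `ultrametric = TRUE`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- if (n_tips == 2) {
    ape::read.tree(text = "(sp01:1,sp02:1);")
  } else {
    t <- ape::rphylo(n_tips, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(t)[seq_len(n_tips)])
    t$edge.length <- t$edge.length / depth
    t$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    t
  }
  attr(tree, "ultrametric") <- TRUE
  tree
}

#' Evolve niche optima by Brownian motion on a tree
#'
#' Each niche dimension evolves independently by Brownian motion with rate
#' `sigma2` along the branches, starting from the root optimum; tip-to-tip
#' covariance equals `sigma2` times shared path length from the root.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param sigma2 Brownian rate (variance accumulated per unit branch length).
#' @param root_optimum numeric vector, one entry per niche dimension.
#' @param seed RNG seed.
#' @return matrix of optima, one row per tip, one column per dimension.
#' @export
evolve_niches <- function(tree, sigma2, root_optimum, seed = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- length(root_optimum)
  out <- vapply(seq_len(k), function(j) {
    if (sigma2 == 0) stats::setNames(rep(root_optimum[j],
                                         length(tree$tip.label)),
                                     tree$tip.label)
    else ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                         root.value = root_optimum[j])
  }, numeric(length(tree$tip.label)))
  out <- matrix(out, ncol = k,
                dimnames = list(tree$tip.label,
                                paste0("dim", seq_len(k))))
  out
}

#' Sample species occurrences from Gaussian niche suitability
#'
#' For each species, cells are drawn without replacement with probability
#' proportional to `exp(-||e(cell) - optimum||^2 / (2 tau^2))` over the
#' niche layers; records are placed at cell centers. As `tau` grows the
#' draw approaches uniform over the valid cells.
#'
#' @param stack an [env_stack()].
#' @param optima an [evolve_niches()] matrix (rows = species); columns map to
#'   the first `ncol(optima)` continuous layers of the stack.
#' @param tau niche breadth (> 0), in environmental units.
#' @param n_per_species records per species.
#' @param seed RNG seed.
#' @return cell-assigned occurrence data frame (`species`, `longitude`,
#'   `latitude`, `row`, `col`, `cell`).
#' @export
sample_occurrences <- function(stack, optima, tau, n_per_species, seed = NULL) {
  stopifnot(tau > 0, n_per_species >= 1)
  cont <- stack$names[stack$kinds == "continuous"]
  k <- ncol(optima)
  if (k > length(cont)) stop("more niche dimensions than continuous layers")
  E <- env_values(stack, layers = cont[seq_len(k)])
  ids <- attr(E, "cell_ids")
  if (n_per_species > length(ids))
    stop("n_per_species exceeds the number of valid cells")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(rownames(optima), function(sp) {
    d2 <- rowSums((E - matrix(optima[sp, ], nrow(E), k, byrow = TRUE))^2)
    w <- exp(-d2 / (2 * tau^2))
    cells <- sample(ids, n_per_species, prob = w / sum(w))
    xy <- cell_centers(stack, cells)
    rc <- cell_rowcol(cells, stack$ncols)
    data.frame(species = sp, longitude = xy[, "x"], latitude = xy[, "y"],
               row = rc[, "row"], col = rc[, "col"], cell = cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a background pool for a synthetic world
#'
#' `"union"` mode pools the unique cells of every species' occurrences (the
#' target-group analogue: localities where any member of the clade was
#' collected); `"uniform"` draws `n_pool` unique valid cells uniformly.
#'
#' @param world a [simulate_world()] result (or a list with `env` and
#'   `occurrences`).
#' @param mode `"union"` or `"uniform"`.
#' @param n_pool pool size for `"uniform"` mode.
#' @param seed RNG seed (`"uniform"` mode).
#' @return a [background_pool()].
#' @export
make_background_pool <- function(world, mode = c("union", "uniform"),
                                 n_pool = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "union") {
    cells <- unique(world$occurrences$cell)
    if (!length(cells)) stop("no occurrences to pool")
    background_pool(cells, world$env, provenance = "union of species occurrence cells")
  } else {
    ids <- valid_cells(world$env)
    if (n_pool > length(ids)) stop("n_pool exceeds the number of valid cells")
    if (!is.null(seed)) set.seed(seed)
    background_pool(sample(ids, n_pool), world$env,
                    provenance = sprintf("uniform draw of %d valid cells", n_pool))
  }
}

#' Simulate a complete synthetic world
#'
#' Landscape, chronogram, Brownian niche optima, occurrences and
#' target-group pool, with the full parameterization and seed recorded.
#' Sub-seeds for each generation stage are derived deterministically from
#' `seed`.
#'
#' @param n_rows,n_cols,n_continuous,n_categorical,smoothness landscape
#'   parameters (see [make_env_stack()]).
#' @param n_tips number of species.
#' @param k_niche number of niche dimensions (first `k_niche` continuous
#'   layers carry the signal).
#' @param sigma2 Brownian rate of niche evolution on the unit-depth tree.
#' @param tau niche breadth.
#' @param n_per_species occurrence records per species.
#' @param pool_mode `"union"` or `"uniform"` (see [make_background_pool()]).
#' @param n_pool pool size for `"uniform"` mode.
#' @param seed master seed.
#' @param shuffle_niches detach niches from the phylogeny by randomly
#'   reassigning the evolved optima to tips (null worlds for calibration).
#' @return object of class `synthetic_world`: `env`, `tree`, `optima`,
#'   `occurrences`, `pool`, `params`.
#' @export
simulate_world <- function(n_rows = 64, n_cols = 64, n_continuous = 4,
                           n_categorical = 1, smoothness = 6, n_tips = 16,
                           k_niche = 2, sigma2 = 0.1, tau = 0.15,
                           n_per_species = 30, pool_mode = "union",
                           n_pool = NULL, seed = 1, shuffle_niches = FALSE) {
  seed <- as.integer(seed)
  sub <- function(i)
    as.integer((as.numeric(seed) * 7 + i * 1000003) %% 2147483647)
  env <- make_env_stack(n_rows, n_cols, n_continuous, n_categorical,
                        smoothness, seed = sub(1))
  tree <- simulate_tree(n_tips, seed = sub(2))
  optima <- evolve_niches(tree, sigma2, rep(0.5, k_niche), seed = sub(3))
  if (shuffle_niches) {
    set.seed(sub(4))
    rownames(optima) <- rownames(optima)[sample.int(nrow(optima))]
    optima <- optima[tree$tip.label, , drop = FALSE]
  }
  occ <- sample_occurrences(env, optima, tau, n_per_species, seed = sub(5))
  world <- list(env = env, tree = tree, optima = optima, occurrences = occ)
  world$pool <- make_background_pool(world, mode = pool_mode, n_pool = n_pool,
                                     seed = sub(6))
  world$params <- list(n_rows = n_rows, n_cols = n_cols,
                       n_continuous = n_continuous,
                       n_categorical = n_categorical,
                       smoothness = smoothness, n_tips = n_tips,
                       k_niche = k_niche, sigma2 = sigma2, tau = tau,
                       n_per_species = n_per_species, pool_mode = pool_mode,
                       n_pool = n_pool, seed = seed,
                       shuffle_niches = shuffle_niches)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_world: %dx%d grid (%d cont + %d cat layers), %d tips, sigma2 = %g, tau = %g, %d rec/species, pool %d cells, seed %d\n",
              p$n_rows, p$n_cols, p$n_continuous, p$n_categorical, p$n_tips,
              p$sigma2, p$tau, p$n_per_species, length(x$pool$cells), p$seed))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Rasters as ESRI ASCII grids, occurrences and pool as CSV, tree as Newick,
#' true optima as CSV, parameters as YAML.
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in world$env$names)
    write_asc(world$env$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  utils::write.csv(world$occurrences[, c("species", "longitude", "latitude")],
                   file.path(dir, "occurrences.csv"), row.names = FALSE)
  xy <- cell_centers(world$env, world$pool$cells)
  utils::write.csv(data.frame(species = "pool", longitude = xy[, "x"],
                              latitude = xy[, "y"]),
                   file.path(dir, "pool.csv"), row.names = FALSE)
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(data.frame(species = rownames(world$optima),
                              world$optima),
                   file.path(dir, "optima.csv"), row.names = FALSE)
  yaml::write_yaml(world$params, file.path(dir, "params.yml"))
  invisible(dir)
}
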
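test_that("env stacks enforce shared geometry and union nodata masks", {
  a <- raster_grid(matrix(1:100, 10, 10), name = "a")
  bv <- matrix(1:100, 10, 10); bv[3, 4] <- NA
  b <- raster_grid(bv, name = "b")
  st <- env_stack(list(a, b))
  expect_equal(length(st$layers), 2)
  expect_false(st$mask[3, 4])
  expect_equal(sum(st$mask), 99)

  off <- raster_grid(matrix(1:100, 10, 10), cellsize = 2, name = "off")
  expect_error(env_stack(list(a, off)), "geometry mismatch.*off")
  allna <- raster_grid(matrix(NA_real_, 10, 10), name = "allna")
  expect_error(env_stack(list(allna)), "empty domain")
})

test_that("ESRI ASCII grids round-trip through write and read", {
  v <- matrix(runif(30), 5, 6); v[2, 3] <- NA
  g <- raster_grid(v, xmin = -70, ymin = -10, cellsize = 0.25, name = "bio1")
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(g, path)
  g2 <- read_asc(path, name = "bio1")
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$xmin, -70)
  expect_equal(g2$cellsize, 0.25)
  expect_error(read_asc(tempfile()), "cannot read")
})

test_that("cell assignment uses the half-open convention and drops outsiders", {
  st <- env_stack(list(raster_grid(matrix(1, 4, 4), name = "e")))
  occ <- data.frame(
    species = "sp",
    longitude = c(0.5, 1.0, 3.999, 5.0, 2.5),
    latitude  = c(3.5, 2.0, 0.001, 1.0, -1.0))
  out <- assign_cells(occ, st, quiet = TRUE)
  # point at a cell center
  expect_equal(out$row[1], 1); expect_equal(out$col[1], 1)
  # x on the shared boundary between columns 1 and 2 -> higher column
  expect_equal(out$col[2], 2)
  expect_equal(nrow(out), 3)              # two points outside are dropped
  expect_equal(attr(out, "n_dropped"), 2)
  # re-assigning the centers of assigned cells returns the same cells
  ctr <- cell_centers(st, out$cell)
  again <- assign_cells(data.frame(species = "sp", longitude = ctr[, "x"],
                                   latitude = ctr[, "y"]), st, quiet = TRUE)
  expect_equal(again$cell, out$cell)
})

test_that("deduplication keeps one record per species-cell and is idempotent", {
  st <- env_stack(list(raster_grid(matrix(1, 4, 4), name = "e")))
  occ <- data.frame(
    species = c("a", "a", "a", "a", "a", "b"),
    longitude = c(0.5, 0.6, 1.5, 2.5, 3.5, 0.5),
    latitude  = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  occ <- assign_cells(occ, st, quiet = TRUE)
  d1 <- deduplicate(occ, quiet = TRUE)
  expect_equal(nrow(d1), 5)               # a keeps 4 cells, b keeps its cell
  expect_equal(attr(d1, "n_removed"), 1)
  expect_equal(sum(d1$species == "b"), 1) # different species may share a cell
  d2 <- deduplicate(d1, quiet = TRUE)
  expect_equal(d2[names(d1)], d1[names(d1)])
  expect_equal(attr(d2, "n_removed"), 0)
  expect_error(deduplicate(data.frame(species = "x")), "cell assignment")
})

test_that("species with fewer unique localities than the minimum are excluded", {
  occ <- data.frame(species = rep(c("four", "three"), c(4, 3)),
                    cell = c(1:4, 11:13))
  flt <- filter_min_localities(occ, 4, quiet = TRUE)
  expect_equal(flt$retained, "four")
  expect_equal(flt$excluded$species, "three")
  expect_equal(flt$excluded$n_localities, 3)
  all_in <- filter_min_localities(occ, 1, quiet = TRUE)
  expect_setequal(all_in$retained, c("four", "three"))
})

test_that("correlated variable pruning matches a brute-force Pearson oracle", {
  st <- toy_stack(n = 5, layers = 3, seed = 4)
  # add an exact copy of layer 1 -> must lose one of the two
  dup <- st$layers[[1]]; dup$name <- "copy"
  st4 <- env_stack(c(st$layers, list(dup)))
  sel <- select_variables(st4, threshold = 0.7)
  expect_true(xor("env01" %in% sel$stack$names, "copy" %in% sel$stack$names))
  expect_true(any(abs(sel$log$r - 1) < 1e-12, na.rm = TRUE))

  # brute-force: recompute all surviving pairwise correlations by hand
  E <- env_values(sel$stack)
  nm <- colnames(E)
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) for (j in (i + 1):length(nm)) {
      r <- pearson_brute(E[, i], E[, j])
      expect_lt(abs(r), 0.7)
    }
  }
  # identity when nothing is correlated above threshold
  sel2 <- select_variables(sel$stack, threshold = 0.7)
  expect_equal(sel2$stack$names, sel$stack$names)
  expect_equal(nrow(sel2$log), 0)
})

test_that("zero-variance layers are removed with a warning", {
  flat <- raster_grid(matrix(5, 10, 10), name = "flat")
  st <- env_stack(c(toy_stack(n = 10, layers = 2, seed = 21)$layers,
                    list(flat)))
  expect_warning(sel <- select_variables(st), "zero-variance")
  expect_false("flat" %in% sel$stack$names)
})

test_that("occurrence CSV reading validates its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,longitude,latitude\nsp1,-70.5,-3.25", path)
  occ <- read_occurrences(path)
  expect_equal(occ$species, "sp1")
  writeLines("longitude,latitude\n-70.5,-3.25", path)
  expect_error(read_occurrences(path), "species")
  pool <- read_occurrences(path, require_species = FALSE)
  expect_equal(pool$species, "pool")
})
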
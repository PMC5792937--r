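#' Pair niche overlap with patristic distance
#'
#' Builds the paired observations of the conservatism test: one row per
#' unordered pair of species present in both the overlap and the distance
#' matrix. Species missing from either matrix are dropped and listed in the
#' `dropped` attribute.
#'
#' @param overlap a [pairwise_overlap()] matrix.
#' @param dist a [patristic_matrix()].
#' @return data frame with columns `sp1`, `sp2`, `overlap`, `distance`;
#'   attribute `dropped` lists species absent from one matrix.
#' @export
paired_values <- function(overlap, dist) {
  shared <- intersect(rownames(overlap), rownames(dist))
  dropped <- union(setdiff(rownames(overlap), shared),
                   setdiff(rownames(dist), shared))
  if (length(shared) < 2)
    stop("fewer than two species shared between the matrices")
  if (length(dropped))
    pn_log("paired_values: dropped species absent from one matrix: %s",
           paste(dropped, collapse = ", "))
  idx <- which(upper.tri(diag(length(shared))), arr.ind = TRUE)
  out <- data.frame(sp1 = shared[idx[, 1]], sp2 = shared[idx[, 2]],
                    overlap = overlap[shared, shared][idx],
                    distance = dist[shared, shared][idx],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Pearson correlation test for niche conservatism
#'
#' Correlates pairwise overlap with pairwise patristic distance, treating
#' the pairs as independent observations: Pearson r with a two-sided p-value
#' from the t transform on `n_pairs - 2` degrees of freedom. A negative
#' correlation (overlap decaying with phylogenetic distance) is the
#' conservatism signal. Pairwise values share species and are not truly
#' independent; see [mantel_test()] for a permutation companion.
#'
#' @param pairs a [paired_values()] data frame (>= 3 pairs).
#' @return object of class `conservatism_result`: `n_pairs`, `r`, `r2`, `p`,
#'   `species`.
#' @export
pearson_test <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least three pairs")
  if (stats::sd(pairs$overlap) == 0 || stats::sd(pairs$distance) == 0)
    stop("undefined correlation: a variable is constant")
  ct <- stats::cor.test(pairs$overlap, pairs$distance, method = "pearson")
  structure(
    list(n_pairs = nrow(pairs), r = unname(ct$estimate),
         r2 = unname(ct$estimate)^2, p = ct$p.value,
         species = sort(unique(c(pairs$sp1, pairs$sp2)))),
    class = "conservatism_result")
}

#' @export
print.conservatism_result <- function(x, ...) {
  cat(sprintf("conservatism_result: %d pairs (%d species), r = %.4f, R^2 = %.4f, p = %.4g%s\n",
              x$n_pairs, length(x$species), x$r, x$r2, x$p,
              if (!is.null(x$mantel_p)) sprintf(", Mantel p = %.4g", x$mantel_p) else ""))
  invisible(x)
}

#' Mantel permutation test of the overlap-distance association
#'
#' Permutes the species labels of the distance matrix and recomputes the
#' pairwise Pearson r; the two-sided p-value is
#' `(1 + #(|r_perm| >= |r_obs|)) / (1 + n_perm)`. Unlike [pearson_test()],
#' this respects the non-independence of pairwise values.
#'
#' @param overlap a [pairwise_overlap()] matrix.
#' @param dist a [patristic_matrix()] sharing >= 4 species with `overlap`.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(overlap, dist, n_perm = 999, seed = NULL) {
  shared <- intersect(rownames(overlap), rownames(dist))
  if (length(shared) < 4) stop("need at least four shared species")
  O <- overlap[shared, shared]
  D <- dist[shared, shared]
  ut <- upper.tri(O)
  r_obs <- stats::cor(O[ut], D[ut])
  if (!is.null(seed)) set.seed(seed)
  n <- length(shared)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(O[ut], D[p, p][ut])
  }, numeric(1))
  list(r = r_obs,
       p = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm),
       n_perm = n_perm)
}

#' Full conservatism test
#'
#' Pairs the matrices, runs the Pearson test, and optionally adds the Mantel
#' permutation p-value.
#'
#' @inheritParams mantel_test
#' @param run_mantel add a Mantel permutation p (default `FALSE`: the
#'   pairwise Pearson test is the primary statistic).
#' @return a `conservatism_result` (with `mantel_p` when requested).
#' @export
conservatism_test <- function(overlap, dist, run_mantel = FALSE,
                              n_perm = 999, seed = NULL) {
  res <- pearson_test(paired_values(overlap, dist))
  if (run_mantel)
    res$mantel_p <- mantel_test(overlap, dist, n_perm = n_perm, seed = seed)$p
  res
}
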
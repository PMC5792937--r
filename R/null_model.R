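#' Build a target-group background pool
#'
#' The pool is the set of unique grid cells where any member of a broader
#' reference clade (the "target group") has been collected. Drawing null
#' localities from this pool rather than from the whole map keeps the null
#' model subject to the same collecting effort and spatial bias as the real
#' records.
#'
#' @param occ occurrence data frame (any species labels; a cell-assigned
#'   pool file also works), or an integer vector of cell ids.
#' @param stack an [env_stack()]; pool cells outside the valid domain are
#'   rejected at construction.
#' @param provenance free-text note carried in the result.
#' @return object of class `background_pool`: list with unique `cells` and
#'   `provenance`.
#' @export
background_pool <- function(occ, stack, provenance = "") {
  cells <- if (is.data.frame(occ)) {
    if (is.null(occ$cell)) occ <- assign_cells(occ, stack, quiet = TRUE)
    occ$cell
  } else as.integer(occ)
  cells <- unique(cells)
  ok <- cells %in% valid_cells(stack)
  if (any(!ok))
    pn_log("background_pool: rejected %d cell(s) outside the valid domain", sum(!ok))
  cells <- cells[ok]
  if (!length(cells)) stop("background pool is empty after domain filtering")
  structure(list(cells = cells, provenance = provenance),
            class = "background_pool")
}

#' Null distribution of AUC from random pool localities
#'
#' For each of `R` replicates, draws `n` localities without replacement from
#' the target-group pool, fits an SDM with exactly the same feature matrix
#' and fitting configuration as the observed model, and records its
#' presence-versus-background AUC. Replicates differ only in their
#' localities.
#'
#' @param pool a [background_pool()].
#' @param n number of localities per replicate (the observed species'
#'   locality count).
#' @param R number of replicates (default 100).
#' @param features the [build_features()] matrix used for the observed model.
#' @param seed RNG seed; the replicate set is fully reproducible from it.
#' @param ... fitting arguments passed to [fit_maxent()].
#' @return ascending numeric vector of `R` replicate AUCs.
#' @export
null_auc_distribution <- function(pool, n, R = 100, features, seed = NULL, ...) {
  stopifnot(inherits(pool, "background_pool"))
  if (n > length(pool$cells))
    stop("n (", n, ") exceeds the pool size (", length(pool$cells), ")")
  if (!is.null(seed)) set.seed(seed)
  aucs <- vapply(seq_len(R), function(r) {
    cells <- sample(pool$cells, n)
    fit_species_sdm(features, cells, ...)$auc
  }, numeric(1))
  sort(aucs)
}

#' 95th-percentile threshold of a replicate AUC distribution
#'
#' The replicate AUCs are sorted ascending and the `ceil(0.95 R)`-th element
#' is taken as the estimate of the 95th percentile — for `R = 100`, exactly
#' the 95th element, with no interpolation.
#'
#' @param replicates numeric vector of replicate AUCs.
#' @return the order-statistic threshold.
#' @export
percentile_threshold <- function(replicates) {
  if (!length(replicates)) stop("empty replicate list")
  sort(replicates)[ceiling(0.95 * length(replicates))]
}

#' Null-model significance test of an SDM
#'
#' The observed model is significantly different from random if its AUC is
#' strictly greater than the 95th-percentile threshold of the null AUC
#' distribution.
#'
#' @param observed observed AUC.
#' @param replicates replicate AUC vector (any order).
#' @param seed seed used to generate the replicates (recorded only).
#' @return object of class `null_result`: `observed`, sorted `replicates`,
#'   `R`, `threshold`, `significant`, `seed`.
#' @export
null_model_test <- function(observed, replicates, seed = NULL) {
  replicates <- sort(replicates)
  threshold <- percentile_threshold(replicates)
  structure(
    list(observed = observed, replicates = replicates,
         R = length(replicates), threshold = threshold,
         significant = observed > threshold, seed = seed),
    class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("null_result: observed AUC %.4f vs 95th-percentile threshold %.4f (R = %d) -> %s\n",
              x$observed, x$threshold, x$R,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
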
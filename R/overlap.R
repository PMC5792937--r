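#' Hellinger's I niche overlap between two suitability surfaces
#'
#' `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)` over the shared cells, for two
#' relative-probability surfaces each summing to 1: 1 for identical
#' surfaces, 0 for disjoint supports.
#'
#' @param p,q [predict_raw()] surfaces or plain probability vectors on the
#'   same cell set. When masks differ, surfaces are restricted to the
#'   intersection of their valid cells and renormalized. Non-normalized
#'   vectors are renormalized with a warning.
#' @return overlap I in \[0, 1\].
#' @export
hellinger_I <- function(p, q) {
  if (inherits(p, "suitability") && inherits(q, "suitability")) {
    shared <- intersect(p$cell_ids, q$cell_ids)
    if (!length(shared)) stop("surfaces share no valid cells")
    if (length(shared) < length(p$cell_ids) ||
        length(shared) < length(q$cell_ids)) {
      pv <- p$p[match(shared, p$cell_ids)]
      qv <- q$p[match(shared, q$cell_ids)]
      pv <- pv / sum(pv); qv <- qv / sum(qv)
    } else {
      if (!identical(p$cell_ids, q$cell_ids))
        stop("surfaces are defined on different cell orderings")
      pv <- p$p; qv <- q$p
    }
  } else if (is.numeric(p) && is.numeric(q)) {
    if (length(p) != length(q)) stop("surfaces differ in length")
    pv <- p; qv <- q
  } else stop("p and q must both be suitability surfaces or numeric vectors")
  if (any(pv < 0) || any(qv < 0)) stop("negative probabilities")
  for (nm in c("p", "q")) {
    v <- if (nm == "p") pv else qv
    if (abs(sum(v) - 1) > 1e-6) {
      warning("surface '", nm, "' does not sum to 1; renormalizing")
      if (nm == "p") pv <- v / sum(v) else qv <- v / sum(v)
    }
  }
  I <- 1 - 0.5 * sum((sqrt(pv) - sqrt(qv))^2)
  min(max(I, 0), 1)
}

#' Pairwise niche overlap matrix
#'
#' @param maps named list of [predict_raw()] surfaces (>= 2) on a shared
#'   domain.
#' @return symmetric matrix of Hellinger's I with unit diagonal, labelled by
#'   species.
#' @export
pairwise_overlap <- function(maps) {
  if (length(maps) < 2) stop("need at least two suitability maps")
  nm <- names(maps) %||% paste0("sp", seq_along(maps))
  M <- diag(1, length(maps))
  dimnames(M) <- list(nm, nm)
  for (i in seq_len(length(maps) - 1)) for (j in (i + 1):length(maps)) {
    M[i, j] <- M[j, i] <- hellinger_I(maps[[i]], maps[[j]])
  }
  M
}

#' Within- and between-clade overlap summary
#'
#' Averages pairwise overlap within each clade (over its species pairs) and
#' between each pair of clades (over all cross pairs), reporting the mean and
#' the standard error of the mean. Singleton clades are listed without a
#' within-clade value; a clade with exactly one pair has a mean but no SE.
#'
#' @param overlap a [pairwise_overlap()] matrix.
#' @param partition named character vector mapping every species in the
#'   matrix to a clade/area label.
#' @return data frame with columns `type` (`"within"`/`"between"`),
#'   `clade_a`, `clade_b`, `n_species`, `n_pairs`, `mean_I`, `se_I`.
#' @export
clade_overlap_summary <- function(overlap, partition) {
  sp <- rownames(overlap)
  if (!all(sp %in% names(partition)))
    stop("partition lacks labels for: ",
         paste(setdiff(sp, names(partition)), collapse = ", "))
  partition <- partition[sp]
  clades <- unique(unname(partition))
  rows <- list()
  pair_vals <- function(a, b) {
    sa <- sp[partition == a]; sb <- sp[partition == b]
    if (a == b) {
      if (length(sa) < 2) return(numeric())
      overlap[sa, sa][upper.tri(diag(length(sa)))]
    } else as.vector(overlap[sa, sb, drop = FALSE])
  }
  for (cl in clades) {
    v <- pair_vals(cl, cl)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "within", clade_a = cl, clade_b = cl,
      n_species = sum(partition == cl), n_pairs = length(v),
      mean_I = if (length(v)) mean(v) else NA_real_,
      se_I = sem(v), stringsAsFactors = FALSE)
  }
  if (length(clades) >= 2) {
    for (i in seq_len(length(clades) - 1)) for (j in (i + 1):length(clades)) {
      v <- pair_vals(clades[i], clades[j])
      rows[[length(rows) + 1L]] <- data.frame(
        type = "between", clade_a = clades[i], clade_b = clades[j],
        n_species = NA_integer_, n_pairs = length(v),
        mean_I = mean(v), se_I = sem(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
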
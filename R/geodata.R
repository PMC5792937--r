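#' Read species occurrence records
#'
#' Expects a UTF-8 CSV with header `species,longitude,latitude` (a species
#' column is optional for background-pool files).
#'
#' @param path CSV file.
#' @param require_species if `FALSE`, a missing species column is filled with
#'   `"pool"`.
#' @return data frame with columns `species`, `longitude`, `latitude`.
#' @export
read_occurrences <- function(path, require_species = TRUE) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  names(occ) <- tolower(names(occ))
  if (!all(c("longitude", "latitude") %in% names(occ)))
    stop("occurrence file must have 'longitude' and 'latitude' columns: ", path)
  if (!"species" %in% names(occ)) {
    if (require_species) stop("occurrence file lacks a 'species' column: ", path)
    occ$species <- "pool"
  }
  occ <- occ[, c("species", "longitude", "latitude")]
  if (!all(is.finite(occ$longitude)) || !all(is.finite(occ$latitude)))
    stop("non-finite coordinates in ", path)
  occ
}

#' Assign occurrence records to grid cells
#'
#' Bins coordinates into the stack's grid with a half-open convention on both
#' axes (`[min, max)`): a point on a shared cell edge belongs to the cell
#' with the larger coordinate bin. Records outside the extent or on masked
#' (nodata) cells are dropped; the drop count is attached as attribute
#' `n_dropped` and reported.
#'
#' @param occ occurrence data frame (`species`, `longitude`, `latitude`).
#' @param stack an [env_stack()].
#' @param quiet suppress the log message.
#' @return `occ` with added integer columns `row`, `col`, `cell`.
#' @export
assign_cells <- function(occ, stack, quiet = FALSE) {
  stopifnot(is.data.frame(occ), inherits(stack, "env_stack"))
  cs <- stack$cellsize
  colx <- floor((occ$longitude - stack$xmin) / cs) + 1
  rowy <- stack$nrows - floor((occ$latitude - stack$ymin) / cs)
  inside <- colx >= 1 & colx <= stack$ncols & rowy >= 1 & rowy <= stack$nrows
  valid <- inside
  valid[inside] <- stack$mask[cbind(rowy[inside], colx[inside])]
  dropped <- sum(!valid)
  out <- occ[valid, , drop = FALSE]
  out$row <- as.integer(rowy[valid])
  out$col <- as.integer(colx[valid])
  out$cell <- cell_id(out$row, out$col, stack$ncols)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  if (!quiet && dropped > 0)
    pn_log("assign_cells: dropped %d record(s) outside the extent or on nodata cells", dropped)
  out
}

#' Remove duplicate localities
#'
#' Records of the same species falling in the same grid cell are collapsed to
#' one: after deduplication each (species, cell) pair is unique. Different
#' species may share a cell.
#'
#' @param occ cell-assigned occurrences (see [assign_cells()]).
#' @param quiet suppress the log message.
#' @return deduplicated data frame; attribute `n_removed` counts removals.
#' @export
deduplicate <- function(occ, quiet = FALSE) {
  if (is.null(occ$cell))
    stop("records have no cell assignment; run assign_cells() first")
  keep <- !duplicated(paste(occ$species, occ$cell, sep = "\r"))
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  if (!quiet)
    pn_log("deduplicate: %d unique record(s) retained, %d duplicate(s) removed",
           nrow(out), sum(!keep))
  out
}

#' Filter species by number of unique localities
#'
#' Species represented at fewer than `min_localities` unique cells are
#' excluded from modelling (default 4).
#'
#' @param occ deduplicated, cell-assigned occurrences.
#' @param min_localities minimum unique localities per species.
#' @param quiet suppress the log message.
#' @return list with `occurrences` (retained records), `retained` (species),
#'   and `excluded` (data frame of species and locality counts).
#' @export
filter_min_localities <- function(occ, min_localities = 4, quiet = FALSE) {
  counts <- table(occ$species)
  retained <- names(counts)[counts >= min_localities]
  excluded <- data.frame(species = names(counts)[counts < min_localities],
                         n_localities = as.integer(counts[counts < min_localities]),
                         stringsAsFactors = FALSE)
  out <- occ[occ$species %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  if (!quiet)
    pn_log("filter_min_localities: %d species retained, %d excluded (< %d unique localities)",
           length(retained), nrow(excluded), min_localities)
  list(occurrences = out, retained = retained, excluded = excluded)
}

#' Prune correlated environmental variables
#'
#' Pearson correlations are computed between all layer pairs over the jointly
#' valid cells (categorical layers enter on their numeric codes). Pairs with
#' `|r| >= threshold` are visited in descending `|r|`; for each pair whose
#' members both survive so far, the later-listed layer is dropped. Layers
#' with zero variance are removed first with a warning (their correlation is
#' undefined).
#'
#' @param stack an [env_stack()].
#' @param threshold absolute Pearson correlation above which one layer of a
#'   pair is removed (default 0.7).
#' @return list with `stack` (reduced [env_stack()]) and `log` (data frame of
#'   removals: `removed`, `kept`, `r`).
#' @export
select_variables <- function(stack, threshold = 0.7) {
  X <- env_values(stack)
  nm <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  removal <- data.frame(removed = character(), kept = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  zero <- nm[sds == 0]
  if (length(zero)) {
    warning("zero-variance layer(s) removed: ", paste(zero, collapse = ", "))
    removal <- rbind(removal, data.frame(removed = zero, kept = NA_character_,
                                         r = NA_real_))
  }
  alive <- setdiff(nm, zero)
  if (length(alive) >= 2) {
    R <- stats::cor(X[, alive, drop = FALSE])
    pr <- which(upper.tri(R) & abs(R) >= threshold, arr.ind = TRUE)
    if (nrow(pr)) {
      ord <- order(-abs(R[pr]))
      pr <- pr[ord, , drop = FALSE]
      dead <- character()
      for (k in seq_len(nrow(pr))) {
        a <- alive[pr[k, 1]]; b <- alive[pr[k, 2]]
        if (a %in% dead || b %in% dead) next
        # drop the later-listed layer of the pair
        dead <- c(dead, b)
        removal <- rbind(removal, data.frame(removed = b, kept = a,
                                             r = R[pr[k, 1], pr[k, 2]]))
      }
      alive <- setdiff(alive, dead)
    }
  }
  keep <- stack$names %in% alive
  if (!any(keep)) stop("variable selection removed every layer")
  list(stack = env_stack(stack$layers[keep]), log = removal)
}
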
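#' Build the feature matrix of a maxent model
#'
#' Continuous layers are rescaled to \[0, 1\] over the valid cells; feature
#' classes expand them into the model's design matrix. In `"auto"` mode the
#' enabled classes follow the presence count: linear always, quadratic from
#' 10 presences, hinge from 15, threshold and product from 80 (the reference
#' defaults for "auto features"). Categorical layers always expand to one
#' 0/1 indicator per observed category code; a layer with a single observed
#' code is dropped with a warning (constant feature).
#'
#' @param stack an [env_stack()].
#' @param n_presences number of presence localities (drives `"auto"` mode).
#' @param mode `"auto"` or `"explicit"`.
#' @param classes character vector of classes for `"explicit"` mode, among
#'   `"linear"`, `"quadratic"`, `"product"`, `"hinge"`, `"threshold"`.
#' @param n_knots number of evenly spaced knots per layer for hinge and
#'   threshold features (default 50).
#' @param max_background background size cap: when the valid domain exceeds
#'   it, a seed-controlled uniform sample of cells is used as background.
#'   Presence cells must be added back via `extra_cells` when they fall
#'   outside the sample.
#' @param extra_cells cell ids always kept in the background (e.g. presence
#'   cells under subsampling).
#' @param seed RNG seed for background subsampling.
#' @return object of class `feature_matrix`: list with `X` (cells x features),
#'   `cell_ids`, `descriptors` (data frame: `class`, `layer`, `knot`,
#'   `category`), `ranges` (per-layer min/max used for scaling) and geometry.
#' @export
build_features <- function(stack, n_presences, mode = c("auto", "explicit"),
                           classes = NULL, n_knots = 50,
                           max_background = 10000, extra_cells = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_presences >= 1)
  if (mode == "auto") {
    classes <- "linear"
    if (n_presences >= 10) classes <- c(classes, "quadratic")
    if (n_presences >= 15) classes <- c(classes, "hinge")
    if (n_presences >= 80) classes <- c(classes, "threshold", "product")
  } else if (is.null(classes)) {
    stop("explicit mode needs a `classes` vector")
  }
  classes <- match.arg(classes, c("linear", "quadratic", "product",
                                  "hinge", "threshold"),
                       several.ok = TRUE)
  E <- env_values(stack)
  ids <- attr(E, "cell_ids")
  if (length(ids) > max_background) {
    if (!is.null(seed)) set.seed(seed)
    keep_ids <- sort(unique(c(sample(ids, max_background),
                              intersect(extra_cells, ids))))
    E <- E[match(keep_ids, ids), , drop = FALSE]
    ids <- keep_ids
  }
  cont <- stack$names[stack$kinds == "continuous"]
  cat_ <- stack$names[stack$kinds == "categorical"]

  ranges <- NULL
  S <- NULL                         # scaled continuous values
  if (length(cont)) {
    lo <- apply(E[, cont, drop = FALSE], 2, min)
    hi <- apply(E[, cont, drop = FALSE], 2, max)
    span <- pmax(hi - lo, .Machine$double.eps)
    S <- sweep(sweep(E[, cont, drop = FALSE], 2, lo), 2, span, "/")
    ranges <- data.frame(layer = cont, min = lo, max = hi,
                         row.names = NULL, stringsAsFactors = FALSE)
  }

  cols <- list()
  desc <- list()
  add <- function(v, class, layer, knot = NA_real_, category = NA_real_) {
    cols[[length(cols) + 1L]] <<- v
    desc[[length(desc) + 1L]] <<- data.frame(class = class, layer = layer,
                                             knot = knot, category = category,
                                             stringsAsFactors = FALSE)
  }

  for (nm in cont) {
    x <- S[, nm]
    if ("linear" %in% classes) add(x, "linear", nm)
    if ("quadratic" %in% classes) add(x^2, "quadratic", nm)
    if ("hinge" %in% classes) {
      knots <- seq(0, 1, length.out = n_knots + 1L)[seq_len(n_knots)]
      for (k in knots) add(pmax(0, (x - k) / (1 - k)), "hinge", nm, knot = k)
    }
    if ("threshold" %in% classes) {
      knots <- seq(0, 1, length.out = n_knots + 2L)[2:(n_knots + 1L)]
      for (k in knots) add(as.numeric(x > k), "threshold", nm, knot = k)
    }
  }
  if ("product" %in% classes && length(cont) >= 2) {
    for (i in seq_len(length(cont) - 1)) for (j in (i + 1):length(cont))
      add(S[, cont[i]] * S[, cont[j]], "product",
          paste(cont[i], cont[j], sep = "*"))
  }
  for (nm in cat_) {
    codes <- sort(unique(E[, nm]))
    if (length(codes) < 2) {
      warning("categorical layer '", nm,
              "' has a single observed category; indicator dropped")
      next
    }
    for (cd in codes) add(as.numeric(E[, nm] == cd), "categorical", nm,
                          category = cd)
  }
  if (!length(cols)) stop("no features could be built from this stack")

  structure(
    list(X = do.call(cbind, cols), cell_ids = ids,
         descriptors = do.call(rbind, desc), ranges = ranges,
         classes = classes, n_knots = n_knots,
         nrows = stack$nrows, ncols = stack$ncols,
         xmin = stack$xmin, ymin = stack$ymin, cellsize = stack$cellsize),
    class = "feature_matrix")
}

# Map cell ids to row indices of the feature matrix; errors on cells outside
# the valid domain.
feature_rows <- function(features, cells) {
  idx <- match(cells, features$cell_ids)
  if (anyNA(idx))
    stop("presence cell(s) outside the valid domain: ",
         paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  idx
}
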
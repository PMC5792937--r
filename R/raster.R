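#' Construct a raster grid
#'
#' A `raster_grid` is the gridded geographical domain of all analyses: a
#' rectangular matrix of cell values with a simple planar georeference
#' (lower-left corner and square cell size). Row 1 of the value matrix is the
#' *top* row of the map (raster convention); `NA` marks nodata cells.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` = nodata.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (map
#'   units; decimal degrees in typical use).
#' @param cellsize cell edge length in map units (cells are square).
#' @param name layer identifier.
#' @param kind `"continuous"` or `"categorical"`. Categorical layers must
#'   hold integer codes.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        name = "layer", kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (cellsize <= 0) stop("`cellsize` must be positive")
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layer '", name, "' contains non-integer codes")
  }
  structure(
    list(values = values, nrows = nrow(values), ncols = ncol(values),
         xmin = xmin, ymin = ymin, cellsize = cellsize,
         name = name, kind = kind),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid '%s' (%s): %d x %d cells, cellsize %g, origin (%g, %g), %d nodata\n",
              x$name, x$kind, x$nrows, x$ncols, x$cellsize, x$xmin, x$ymin,
              sum(is.na(x$values))))
  invisible(x)
}

same_geometry <- function(a, b) {
  a$nrows == b$nrows && a$ncols == b$ncols &&
    isTRUE(all.equal(a$xmin, b$xmin)) && isTRUE(all.equal(a$ymin, b$ymin)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize))
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` format (header keywords `ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by row-major values, north row first.
#'
#' @param path file path.
#' @inheritParams raster_grid
#' @return a [raster_grid()].
#' @export
read_asc <- function(path, name = NULL, kind = "continuous") {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  xll <- hdr$xllcorner %||% (hdr$xllcenter - hdr$cellsize / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - hdr$cellsize / 2)
  if (is.null(xll) || is.null(yll)) stop("missing corner/center in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", found ", length(vals))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_grid(m, xmin = xll, ymin = yll, cellsize = hdr$cellsize,
              name = name %||% sub("\\.[^.]*$", "", basename(path)),
              kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.10g", grid$xmin),
           sprintf("yllcorner %.10g", grid$ymin),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %g", nodata))
  v <- grid$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Build an environmental stack from aligned raster layers
#'
#' Layers must share geometry exactly. The stack's validity mask is the set
#' of cells with a finite value in *every* layer (nodata union is masked).
#'
#' @param layers list of [raster_grid()] objects.
#' @return an object of class `env_stack` with elements `layers`, `kinds`,
#'   `names`, `mask` (logical matrix, `TRUE` = valid) and the shared geometry.
#' @export
env_stack <- function(layers) {
  if (!length(layers)) stop("an environmental stack needs at least one layer")
  for (l in layers) stopifnot(inherits(l, "raster_grid"))
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (!same_geometry(ref, l))
      stop("geometry mismatch: layer '", l$name,
           "' does not align with layer '", ref$name, "'")
  }
  nm <- vapply(layers, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate layer names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(layers) <- nm
  mask <- Reduce(`&`, lapply(layers, function(l) is.finite(l$values)))
  if (!any(mask)) stop("empty domain: no cell is valid in all layers")
  structure(
    list(layers = layers, kinds = vapply(layers, `[[`, "", "kind"),
         names = nm, mask = mask,
         nrows = ref$nrows, ncols = ref$ncols,
         xmin = ref$xmin, ymin = ref$ymin, cellsize = ref$cellsize),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layer(s) on a %d x %d grid (%d valid cells)\n",
              length(x$layers), x$nrows, x$ncols, sum(x$mask)))
  for (i in seq_along(x$layers))
    cat(sprintf("  [%d] %s (%s)\n", i, x$names[i], x$kinds[i]))
  invisible(x)
}

#' Read a stack of ESRI ASCII grids
#'
#' @param paths character vector of `.asc` files.
#' @param kinds per-layer kind, recycled if length 1.
#' @param names optional layer names (defaults to file stems).
#' @return an [env_stack()].
#' @export
read_env_stack <- function(paths, kinds = "continuous", names = NULL) {
  kinds <- rep_len(kinds, length(paths))
  layers <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    layers[[i]] <- read_asc(paths[i], kind = kinds[i],
                            name = if (is.null(names)) NULL else names[i])
  }
  env_stack(layers)
}

# Cell ids are 1-based row-major indices counted from the top-left corner:
# id = (row - 1) * ncols + col, row 1 = north.
cell_id <- function(row, col, ncols) (row - 1L) * ncols + col

cell_rowcol <- function(id, ncols) {
  row <- (id - 1L) %/% ncols + 1L
  col <- (id - 1L) %% ncols + 1L
  cbind(row = row, col = col)
}

#' Valid cell ids of a stack
#' @param stack an [env_stack()].
#' @return integer vector of cell ids (row-major from the top-left).
#' @export
valid_cells <- function(stack) {
  m <- t(stack$mask)              # row-major order
  which(as.vector(m))
}

#' Environmental values at the valid cells
#'
#' @param stack an [env_stack()].
#' @param layers optional subset of layer names.
#' @return numeric matrix, one row per valid cell (in `valid_cells()` order),
#'   one column per layer; attribute `cell_ids` carries the cell ids.
#' @export
env_values <- function(stack, layers = NULL) {
  ids <- valid_cells(stack)
  rc <- cell_rowcol(ids, stack$ncols)
  use <- layers %||% stack$names
  out <- vapply(use, function(nm) stack$layers[[nm]]$values[rc], numeric(nrow(rc)))
  out <- matrix(out, nrow = nrow(rc),
                dimnames = list(NULL, use))
  attr(out, "cell_ids") <- ids
  out
}

#' Coordinates of cell centers
#' @param stack an [env_stack()] (or any object with the shared geometry
#'   fields).
#' @param ids integer cell ids.
#' @return two-column matrix `x`, `y` of center coordinates.
#' @export
cell_centers <- function(stack, ids) {
  rc <- cell_rowcol(ids, stack$ncols)
  x <- stack$xmin + (rc[, "col"] - 0.5) * stack$cellsize
  y <- stack$ymin + (stack$nrows - rc[, "row"] + 0.5) * stack$cellsize
  cbind(x = x, y = y)
}
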
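#' Read a phylogenetic tree
#'
#' Accepts Newick or NEXUS text (auto-detected) from a file or a literal
#' string. The tree must have branch lengths and unique tip labels. An
#' ultrametric flag is auto-detected: root-to-tip depths equal within a
#' relative tolerance of `1e-6` of the tree depth (absorbs chronogram
#' rounding).
#'
#' @param source file path or tree text.
#' @return an [ape::read.tree()] `phylo` object with attribute `ultrametric`.
#' @export
read_tree <- function(source) {
  txt <- if (length(source) == 1 && !grepl("[(;]", source) && file.exists(source))
    paste(readLines(source, warn = FALSE), collapse = "\n") else source
  tree <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
    writeLines(txt, tf)
    ape::read.nexus(tf)
  } else {
    tryCatch(ape::read.tree(text = txt),
             error = function(e) stop("tree parse error: ", conditionMessage(e)))
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) stop("tree parse error: no tree found")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  attr(tree, "ultrametric") <- (max(depths) - min(depths)) <= 1e-6 * max(depths)
  tree
}

is_ultrametric_tree <- function(tree) {
  u <- attr(tree, "ultrametric")
  if (!is.null(u)) return(u)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(depths) - min(depths)) <= 1e-6 * max(depths)
}

#' Patristic distance matrix
#'
#' Entry (i, j) is the sum of branch lengths along the unique path connecting
#' tips i and j ("adding up connecting branches").
#'
#' @param tree a `phylo` object with branch lengths.
#' @param taxa optional subset of tip labels.
#' @return symmetric labelled distance matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree, taxa = NULL) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, tree$tip.label)
    if (length(missing))
      stop("taxa not in tree: ", paste(missing, collapse = ", "))
    D <- D[taxa, taxa, drop = FALSE]
  }
  D
}

#' Crown and stem ages of a clade on a chronogram
#'
#' On an ultrametric tree, a node's age is its depth above the present (tree
#' depth minus root-to-node distance). The crown age of a tip set is the age
#' of its most recent common ancestor (MRCA); the stem age is the age of the
#' MRCA's parent. For a single tip the crown is undefined (reported `NA`)
#' and the stem is the age of the tip's attachment node. When the MRCA is
#' the root, the stem is reported `NA` with a note.
#'
#' @param tree ultrametric `phylo` object.
#' @param tips character vector of tip labels defining the clade.
#' @return data frame with one row: `clade`, `n_tips`, `crown`, `stem`,
#'   `note`.
#' @export
crown_stem_ages <- function(tree, tips) {
  if (!is_ultrametric_tree(tree)) stop("tree is not ultrametric")
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) stop("tips not in tree: ", paste(missing, collapse = ", "))
  if (!length(tips)) stop("empty tip set")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth[seq_len(ntip)])
  age <- total - depth
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  note <- ""
  if (length(tips) == 1) {
    tip <- match(tips, tree$tip.label)
    crown <- NA_real_
    stem <- age[parent_of(tip)]
    note <- "single tip: crown undefined, stem = attachment node age"
  } else {
    mrca <- ape::getMRCA(tree, tips)
    crown <- age[mrca]
    if (mrca == root) {
      stem <- NA_real_
      note <- "MRCA is the root: stem undefined"
    } else stem <- age[parent_of(mrca)]
  }
  data.frame(clade = paste(tips, collapse = "+"), n_tips = length(tips),
             crown = crown, stem = stem, note = note,
             stringsAsFactors = FALSE)
}

#' Crown/stem age table for a set of named clades
#'
#' @param tree ultrametric `phylo`.
#' @param clades named list of tip-label vectors.
#' @return data frame, one row per clade (rownames = clade names).
#' @export
ages_table <- function(tree, clades) {
  out <- do.call(rbind, lapply(clades, function(t) crown_stem_ages(tree, t)))
  out$clade <- names(clades)
  out
}
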
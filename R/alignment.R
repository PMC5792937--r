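#' Read a multiple sequence alignment
#'
#' FASTA or NEXUS (auto-detected). Returns an upper-case character matrix
#' (taxa x sites) over `A,C,G,T`, IUPAC ambiguity codes, `-` and `?`.
#'
#' @param path alignment file.
#' @return character matrix with taxon rownames; class `dna_alignment`.
#' @export
read_alignment <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
    seqs <- ape::read.nexus.data(path)
    rows <- lapply(seqs, function(s) toupper(s))
  } else {
    dna <- ape::read.FASTA(path)
    rows <- lapply(as.character(dna), toupper)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("sequences have unequal lengths; not an alignment: ", path)
  aln <- do.call(rbind, rows)
  as_alignment(aln)
}

#' Construct an alignment from a character matrix
#' @param mat character matrix (taxa x sites) with unique rownames.
#' @return the matrix with class `dna_alignment`.
#' @export
as_alignment <- function(mat) {
  if (is.null(rownames(mat))) stop("alignment needs taxon rownames")
  if (anyDuplicated(rownames(mat))) stop("duplicate taxon labels")
  mat[] <- toupper(mat)
  mat[mat %in% c("N", ".")] <- "?"
  class(mat) <- c("dna_alignment", class(mat))
  mat
}

UNAMBIG <- c("A", "C", "G", "T")

#' Classify alignment sites
#'
#' Per site, only unambiguous nucleotides count (gaps, `?` and IUPAC
#' ambiguity codes are treated as missing). A site is *constant* if at most
#' one state occurs, *parsimony-informative* if at least two states each
#' occur in at least two taxa, and *variable-uninformative* otherwise.
#'
#' @param aln a [read_alignment()] matrix.
#' @param taxa optional taxon subset.
#' @return object of class `site_classification`: `included`, `constant`,
#'   `variable_uninformative`, `parsimony_informative` counts and the
#'   per-site class vector.
#' @export
classify_sites <- function(aln, taxa = NULL) {
  if (!nrow(aln) || !ncol(aln)) stop("empty alignment")
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(aln))
    if (length(missing)) stop("taxa not in alignment: ",
                              paste(missing, collapse = ", "))
    aln <- aln[taxa, , drop = FALSE]
  }
  cls <- apply(aln, 2, function(col) {
    tab <- table(col[col %in% UNAMBIG])
    if (length(tab) <= 1) "constant"
    else if (sum(tab >= 2) >= 2) "parsimony_informative"
    else "variable_uninformative"
  })
  structure(
    list(included = ncol(aln),
         constant = sum(cls == "constant"),
         variable_uninformative = sum(cls == "variable_uninformative"),
         parsimony_informative = sum(cls == "parsimony_informative"),
         site_classes = cls),
    class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf("site_classification: %d included = %d constant + %d variable-uninformative + %d parsimony-informative\n",
              x$included, x$constant, x$variable_uninformative,
              x$parsimony_informative))
  invisible(x)
}

# per-taxon maximal runs of '-' and the span of determined sequence
gap_runs <- function(row) {
  miss <- row %in% c("-", "?")
  if (all(miss)) return(list(first = NA, last = NA, runs = NULL))
  first <- which(!miss)[1]
  last <- max(which(!miss))
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & starts > first & ends < last
  list(first = first, last = last,
       runs = cbind(start = starts[keep], end = ends[keep]))
}

#' Simple binary indel coding
#'
#' Codes internal gaps as presence/absence characters where they can be
#' coded unambiguously: each distinct internal gap (a maximal run of `-`
#' with identical start and end columns across the taxa sharing it) becomes
#' one binary character. A taxon scores `1` if it has exactly that gap, `0`
#' if it has contiguous determined sequence across the span, and `?` if it
#' has a *different* gap overlapping the span (ambiguous homology) or if the
#' span falls in its leading/trailing missing region. Terminal gaps are
#' treated as missing data, never coded.
#'
#' @param aln a [read_alignment()] matrix.
#' @return object of class `indel_matrix`: `characters` (taxa x characters
#'   matrix over `"0"`, `"1"`, `"?"`), and `gaps` (data frame of coded
#'   `start`/`end` columns). Zero characters when the alignment has no
#'   codable internal gap.
#' @export
simple_indel_coding <- function(aln) {
  taxa <- rownames(aln)
  info <- lapply(seq_len(nrow(aln)), function(i) gap_runs(aln[i, ]))
  all_runs <- do.call(rbind, lapply(info, `[[`, "runs"))
  if (is.null(all_runs) || !nrow(all_runs)) {
    return(structure(list(
      characters = matrix(character(), nrow = length(taxa), ncol = 0,
                          dimnames = list(taxa, NULL)),
      gaps = data.frame(start = integer(), end = integer())),
      class = "indel_matrix"))
  }
  gaps <- unique(as.data.frame(all_runs))
  gaps <- gaps[order(gaps$start, gaps$end), , drop = FALSE]
  rownames(gaps) <- NULL
  M <- matrix("?", nrow = length(taxa), ncol = nrow(gaps),
              dimnames = list(taxa, paste0("indel_", gaps$start, "_", gaps$end)))
  for (g in seq_len(nrow(gaps))) {
    s <- gaps$start[g]; e <- gaps$end[g]
    for (i in seq_along(taxa)) {
      gi <- info[[i]]
      if (is.na(gi$first) || gi$first > s || gi$last < e) next   # missing span
      runs <- gi$runs
      exact <- !is.null(runs) && nrow(runs) &&
        any(runs[, "start"] == s & runs[, "end"] == e)
      overlap <- !is.null(runs) && nrow(runs) &&
        any(runs[, "start"] <= e & runs[, "end"] >= s)
      has_q <- any(aln[i, s:e] == "?")
      M[i, g] <- if (exact) "1"
        else if (overlap || has_q) "?"
        else "0"
    }
  }
  structure(list(characters = M, gaps = gaps), class = "indel_matrix")
}

#' Parsimony-informativeness of binary indel characters
#' @param indels a [simple_indel_coding()] result.
#' @return logical vector: `TRUE` where >= 2 taxa score 1 and >= 2 score 0.
#' @export
informative_indels <- function(indels) {
  M <- indels$characters
  if (!ncol(M)) return(logical())
  apply(M, 2, function(col) sum(col == "1") >= 2 && sum(col == "0") >= 2)
}

#' Per-marker character summary
#'
#' Site-class counts and parsimony-informative indel counts per marker,
#' ordered by descending parsimony-informative sites. With
#' `subset = "shared"`, counting is restricted to taxa with determined
#' sequence in every marker (the intersection filter that makes markers
#' comparable).
#'
#' @param alignments named list of [read_alignment()] matrices.
#' @param subset `"shared"` (intersection of taxa with data in all markers)
#'   or `"all"`.
#' @return data frame: `marker`, `n_taxa`, `included`,
#'   `variable_uninformative`, `parsimony_informative`,
#'   `informative_indels`; attribute `taxa` echoes the subset used.
#' @export
marker_summary <- function(alignments, subset = c("shared", "all")) {
  subset <- match.arg(subset)
  if (!length(alignments)) stop("no alignments supplied")
  if (is.null(names(alignments)))
    names(alignments) <- paste0("marker", seq_along(alignments))
  has_data <- function(aln) rownames(aln)[
    apply(aln, 1, function(r) any(r %in% UNAMBIG))]
  taxa <- if (subset == "shared")
    Reduce(intersect, lapply(alignments, has_data))
  else unique(unlist(lapply(alignments, rownames)))
  if (!length(taxa)) stop("no taxa shared across all markers")
  rows <- lapply(names(alignments), function(nm) {
    aln <- alignments[[nm]]
    use <- intersect(taxa, rownames(aln))
    sc <- classify_sites(aln, use)
    ind <- simple_indel_coding(aln[use, , drop = FALSE])
    data.frame(marker = nm, n_taxa = length(use), included = sc$included,
               variable_uninformative = sc$variable_uninformative,
               parsimony_informative = sc$parsimony_informative,
               informative_indels = sum(informative_indels(ind)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$parsimony_informative), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- taxa
  out
}

#' Write an alignment plus indel characters as NEXUS
#'
#' Writes the DNA matrix as a `datatype=dna` block and, when indel
#' characters exist, appends them as a `datatype=standard` block.
#'
#' @param aln a [read_alignment()] matrix.
#' @param indels optional [simple_indel_coding()] result.
#' @param path output file.
#' @export
write_nexus_with_indels <- function(aln, indels = NULL, path) {
  taxa <- rownames(aln)
  pad <- formatC(taxa, width = max(nchar(taxa)), flag = "-")
  lines <- c("#NEXUS", "",
             "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln), ncol(aln)),
             "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
             "  MATRIX")
  lines <- c(lines, paste0("    ", pad, "  ",
                           apply(aln, 1, paste, collapse = "")),
             "  ;", "END;")
  if (!is.null(indels) && ncol(indels$characters)) {
    M <- indels$characters
    lines <- c(lines, "",
               "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NCHAR=%d;", ncol(M)),
               "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
               "  MATRIX")
    lines <- c(lines, paste0("    ", pad, "  ",
                             apply(M, 1, paste, collapse = "")),
               "  ;", "END;")
  }
  writeLines(lines, path)
  invisible(path)
}
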
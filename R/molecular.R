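#' Read / write aligned FASTA
#'
#' Alignments are plain uppercase character matrices (rows = taxa, columns =
#' sites) over `A C G T - ? N`; I/O goes through ape's FASTA reader/writer.
#'
#' @param path FASTA file of aligned, equal-length DNA sequences.
#' @return a character matrix with taxon rownames.
#' @export
read_fasta_alignment <- function(path) {
  dn <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(dn)))
  .validate_alignment(m)
  m
}

#' @rdname read_fasta_alignment
#' @param aln alignment character matrix.
#' @export
write_fasta_alignment <- function(aln, path) {
  .validate_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln)))
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  invisible(path)
}

#' @rdname read_fasta_alignment
#' @details `write_phylip_alignment` writes the relaxed (long-name) PHYLIP
#'   variant for interoperability with ML tools.
#' @export
write_phylip_alignment <- function(aln, path) {
  .validate_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(aln), ncol(aln)), con)
  writeLines(sprintf("%s  %s", rownames(aln),
                     apply(aln, 1, paste, collapse = "")), con)
  invisible(path)
}

.validate_alignment <- function(aln) {
  if (!is.matrix(aln) || ncol(aln) == 0L) stop("empty alignment")
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln)))
    stop("alignment taxa must be unique rownames")
  bad <- setdiff(unique(as.vector(aln)), c("A", "C", "G", "T", "-", "?", "N"))
  if (length(bad)) stop("unexpected symbols: ", paste(bad, collapse = " "))
  invisible(aln)
}

#' Uncorrected pairwise distance
#'
#' Proportion of mismatching sites between two aligned sequences over the
#' comparable columns — those where both symbols are in `A/C/G/T` (pairwise
#' deletion of gaps and ambiguities).
#'
#' @param aln alignment character matrix (see [read_fasta_alignment()]).
#' @param a,b taxon names.
#' @return the p-distance, a proportion in `[0, 1]`.
#' @export
p_distance <- function(aln, a, b) {
  .validate_alignment(aln)
  if (!a %in% rownames(aln)) stop("taxon not in alignment: ", a)
  if (!b %in% rownames(aln)) stop("taxon not in alignment: ", b)
  x <- aln[a, ]; y <- aln[b, ]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable columns between ", a, " and ", b)
  sum(x[ok] != y[ok]) / sum(ok)
}

#' All-pairs distance matrix
#'
#' @param aln alignment character matrix.
#' @param model `"p"` for the uncorrected p-distance (default; the standard
#'   reading of percent-divergence statements in COI barcoding) or `"K2P"`
#'   for the Kimura two-parameter correction (via [ape::dist.dna()]).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
divergence_matrix <- function(aln, model = c("p", "K2P")) {
  model <- match.arg(model)
  .validate_alignment(aln)
  if (model == "K2P") {
    dn <- ape::as.DNAbin(tolower(aln))
    return(as.matrix(ape::dist.dna(dn, model = "K80",
                                   pairwise.deletion = TRUE)))
  }
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- p_distance(aln, rownames(aln)[i], rownames(aln)[j])
  }
  d
}

#' Maximum within-group sequence divergence
#'
#' The largest pairwise divergence among members of a group, in percent —
#' the quantity used to argue that haplotypes of a genus represent a single
#' species when it is small (well under typical interspecific COI
#' divergence).
#'
#' @param aln alignment character matrix.
#' @param group two or more taxon names.
#' @param model see [divergence_matrix()].
#' @return maximum pairwise divergence within the group, in percent.
#' @export
max_intragroup_divergence <- function(aln, group, model = "p") {
  group <- unique(as.character(group))
  if (length(group) < 2L) stop("group needs at least 2 taxa")
  missing <- setdiff(group, rownames(aln))
  if (length(missing)) stop("taxa not in alignment: ",
                            paste(missing, collapse = ", "))
  d <- divergence_matrix(aln[group, , drop = FALSE], model = model)
  100 * max(d)
}

#' Neighbor-joining fixture tree
#'
#' Standard neighbor joining (Q criterion, Studier–Keppler branch lengths)
#' through [ape::nj()], used here to build fixture trees from distance
#' matrices; on an exactly additive matrix NJ recovers the generating
#' unrooted topology and branch lengths.  Negative branch-length estimates
#' (possible on non-additive input) are clamped to zero with a warning and
#' flagged via `attr(tree, "clamped")`.
#'
#' @param d symmetric distance matrix (or `dist`) over at least 3 taxa.
#' @return an unrooted `phylo` object.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
    attr(tr, "clamped") <- TRUE
  } else {
    attr(tr, "clamped") <- FALSE
  }
  tr
}
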
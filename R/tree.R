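#' Parse a Newick string into a phylogenetic tree
#'
#' Thin, validating wrapper around [ape::read.tree()].  Trees are returned as
#' standard `phylo` objects so that they interoperate with the rest of the R
#' phylogenetics ecosystem.  Beyond ape's parser this adds: a structural
#' pre-check that reports the character offset of the first defect (unbalanced
#' parentheses, missing terminal semicolon), rejection of duplicate or empty
#' tip labels, rejection of negative branch lengths, a single-tip special case
#' (`"A;"`), and an `unrooted` attribute flagging inputs whose root is a basal
#' multifurcation.
#'
#' @param text a Newick string (single tree).
#' @return a `phylo` object; `attr(tree, "unrooted")` is `TRUE` when the input
#'   had a basal multifurcation.
#' @seealso [write_newick()], [reroot_edge()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  .newick_syntax_check(text)
  body <- sub(";\\s*$", "", text)
  if (!grepl("[(),]", body)) {
    # single-tip tree: ape cannot parse "A;"
    lab <- sub(":.*$", "", body)
    len <- if (grepl(":", body)) as.numeric(sub("^[^:]*:", "", body)) else NULL
    if (!nzchar(lab)) stop("empty tip label in Newick input")
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = gsub("^'|'$", "", lab),
      Nnode = 1L
    ), class = "phylo", order = "cladewise")
    if (!is.null(len)) tr$edge.length <- len
    attr(tr, "unrooted") <- FALSE
    return(tr)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string")
  .validate_tree(tr)
  attr(tr, "unrooted") <- !ape::is.rooted(tr)
  tr
}

.newick_syntax_check <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick syntax error at offset %d: unmatched ')'", i))
    }
  }
  if (in_quote) stop("Newick syntax error: unterminated quoted label")
  if (depth > 0L)
    stop(sprintf(
      "Newick syntax error at offset %d: %d unclosed '('", nchar(text), depth))
  if (!grepl(";\\s*$", text))
    stop(sprintf("Newick syntax error at offset %d: missing ';'", nchar(text)))
}

.validate_tree <- function(tree) {
  labs <- tree$tip.label
  if (anyDuplicated(labs))
    stop("duplicate tip label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (any(!nzchar(labs)) || anyNA(labs)) stop("empty tip label")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  invisible(tree)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with 10 significant digits so that a
#' parse/write/parse round trip preserves them to well under 1e-9.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when given the string is also written to disk.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    len <- if (!is.null(tree$edge.length))
      paste0(":", format(tree$edge.length[1], digits = 10)) else ""
    s <- paste0(tree$tip.label, len, ";")
  } else {
    s <- ape::write.tree(tree, digits = 10)
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Reroot a tree on a given edge
#'
#' The new root subdivides the chosen edge (at its midpoint when branch
#' lengths are present), leaving the unrooted topology — and hence every
#' tip-to-tip path length — unchanged.
#'
#' @param tree a `phylo` object.
#' @param edge row index into `tree$edge` identifying the edge to root on.
#' @return a rerooted `phylo` object.
#' @export
reroot_edge <- function(tree, edge) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(edge) || length(edge) != 1L || edge < 1 ||
      edge > nrow(tree$edge))
    stop("unknown edge: ", edge)
  edge <- as.integer(edge)
  had_lengths <- !is.null(tree$edge.length)
  work <- tree
  if (!had_lengths) work$edge.length <- rep(1, nrow(work$edge))
  node <- work$edge[edge, 2L]
  root <- ape::Ntip(work) + 1L
  if (node == root) return(tree)
  pos <- work$edge.length[edge] / 2
  out <- phytools::reroot(work, node.number = node, position = pos)
  if (!had_lengths) out$edge.length <- NULL
  out$node.label <- NULL
  out
}

#' Draw a uniform random rooted binary topology
#'
#' Topologies are generated by sequential random addition: each successive
#' tip is inserted on an edge chosen uniformly among the current edges,
#' including the edge above the root, which makes every labelled rooted
#' binary topology on `n` tips equally probable (probability `1/(2n-3)!!`).
#' This is the null-tree model of the randomization test in [signal_test()].
#' No branch lengths are assigned.
#'
#' @param labels character vector of at least 2 unique tip labels.
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @return a rooted binary `phylo` object without branch lengths.
#' @export
random_topology <- function(labels, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("need at least 2 tip labels")
  if (anyDuplicated(labels)) stop("duplicate tip labels")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  e0 <- random_topology_edges(n)  # 0-based, preorder, tips 0..n-1
  .edges_to_phylo(e0, labels)
}

# Convert a 0-based edge list (tips 0..n-1, internals n..2n-2, any row
# order) into an ape phylo: edges are re-emitted in true cladewise
# (depth-first preorder) order and internal nodes renumbered n+1, n+2, ...
# in order of first appearance, ape's canonical form.  An optional third
# column carries branch lengths.
.edges_to_phylo <- function(e0, labels) {
  n <- length(labels)
  m <- 2L * n - 1L
  kids <- vector("list", m)
  for (r in seq_len(nrow(e0)))
    kids[[e0[r, 1L] + 1L]] <- c(kids[[e0[r, 1L] + 1L]], e0[r, 2L] + 1L)
  elen_in <- if (ncol(e0) >= 3L) e0[, 3L] else NULL
  len_of <- NULL
  if (!is.null(elen_in)) {
    len_of <- numeric(m)
    len_of[e0[, 2L] + 1L] <- elen_in
  }
  is_parent <- rep(FALSE, m)
  is_parent[e0[, 1L] + 1L] <- TRUE
  is_child <- rep(FALSE, m)
  is_child[e0[, 2L] + 1L] <- TRUE
  root0 <- which(is_parent & !is_child)[1L]
  map <- integer(m)
  map[seq_len(n)] <- seq_len(n)            # tips keep their order
  map[root0] <- n + 1L
  nxt <- n + 2L
  edge <- matrix(0L, nrow(e0), 2L)
  elen <- numeric(nrow(e0))
  r <- 0L
  emit <- function(v) {   # DFS: each child edge directly before its subtree
    for (c in kids[[v]]) {
      r <<- r + 1L
      if (c > n && map[c] == 0L) { map[c] <<- nxt; nxt <<- nxt + 1L }
      edge[r, ] <<- c(map[v], map[c])
      if (!is.null(len_of)) elen[r] <<- len_of[c]
      if (c > n) emit(c)
    }
  }
  emit(root0)
  tr <- structure(list(edge = edge, tip.label = labels,
                       Nnode = max(edge) - n),
                  class = "phylo", order = "cladewise")
  if (!is.null(len_of)) tr$edge.length <- elen
  tr
}

#' Permute the tip labels of a tree
#'
#' Topology and branch lengths are untouched; the labels are reassigned by a
#' uniform random permutation.  This is the alternative null model
#' (`method = "shuffle_tips"`) of [signal_test()].
#'
#' @param tree a `phylo` object.
#' @param seed optional integer seed.
#' @return a `phylo` object with permuted tip labels.
#' @export
shuffle_tips <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  tree$tip.label <- tree$tip.label[.fisher_yates(length(tree$tip.label))]
  tree
}

# Uniform permutation by Fisher-Yates on the raw uniform stream; kept in
# lock-step with the compiled null-distribution loop so that the fast and
# fallback paths draw identical permutations under the same seed.
.fisher_yates <- function(n) {
  perm <- seq_len(n)
  if (n < 2L) return(perm)
  for (i in n:2L) {
    j <- min(floor(runif(1) * i) + 1L, i)
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
  }
  perm
}

#' Classify a named group as mono-, para- or polyphyletic
#'
#' On the rooted tree, the minimal clade spanning the group is located; the
#' group is *monophyletic* when that clade contains no other tips,
#' *paraphyletic* when the intruding tips themselves form a single clade
#' (removing one nested clade of non-members leaves the group exclusive), and
#' *polyphyletic* otherwise.  Group members absent from the tree are dropped
#' with a warning; a group with fewer than two tips present is
#' `not_assessable`.
#'
#' @param tree a rooted `phylo` object.
#' @param group character vector of tip labels forming the named group.
#' @return an object of class `monophyly_status` with fields `status`
#'   (`"monophyletic"`, `"paraphyletic"`, `"polyphyletic"` or
#'   `"not_assessable"`), `clade_tips` (tips of the minimal spanning clade),
#'   `n_intruders`, `group` (members present in the tree) and `dropped`.
#' @export
monophyly_status <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"))
  group <- unique(as.character(group))
  if (length(group) == 0L) stop("empty group")
  present <- intersect(group, tree$tip.label)
  dropped <- setdiff(group, tree$tip.label)
  if (length(dropped))
    warning("group members absent from tree: ",
            paste(dropped, collapse = ", "))
  if (length(present) < 2L) {
    return(structure(list(status = "not_assessable",
                          clade_tips = present, n_intruders = NA_integer_,
                          group = present, dropped = dropped),
                     class = "monophyly_status"))
  }
  clade <- .spanning_clade_tips(tree, present)
  intruders <- setdiff(clade, present)
  status <- if (length(intruders) == 0L) {
    "monophyletic"
  } else if (length(intruders) == 1L ||
             setequal(.spanning_clade_tips(tree, intruders), intruders)) {
    "paraphyletic"
  } else {
    "polyphyletic"
  }
  structure(list(status = status, clade_tips = clade,
                 n_intruders = length(intruders), group = present,
                 dropped = dropped),
            class = "monophyly_status")
}

.spanning_clade_tips <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (length(idx) == length(tree$tip.label)) return(tree$tip.label)
  mrca <- ape::getMRCA(tree, idx)
  if (is.null(mrca)) return(tips)  # length-1 case: a tip is its own clade
  ape::extract.clade(tree, mrca)$tip.label
}

#' @export
print.monophyly_status <- function(x, ...) {
  cat("Monophyly assessment\n")
  cat("  status:    ", x$status, "\n", sep = "")
  cat("  group size:", length(x$group), "\n")
  if (!is.na(x$n_intruders)) cat("  intruders: ", x$n_intruders, "\n")
  if (length(x$dropped))
    cat("  dropped (not in tree):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Assess several named groups at once
#'
#' @param tree a rooted `phylo` object.
#' @param groups named list of character vectors (group name -> member tips).
#' @return a data.frame with one row per group: `group`, `n_tips`, `status`,
#'   `n_intruders`.
#' @export
monophyly_table <- function(tree, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    st <- suppressWarnings(monophyly_status(tree, groups[[g]]))
    data.frame(group = g, n_tips = length(st$group), status = st$status,
               n_intruders = st$n_intruders, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Matrix of all tip-to-tip path lengths; used by tests and reroot invariants.
tip_distances <- function(tree) {
  stats::cophenetic(tree)
}
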
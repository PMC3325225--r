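#' Step (cost) matrices for discrete-character parsimony
#'
#' `"unordered"` is the unweighted (Fitch) matrix: every change costs 1.
#' `"ordered"` is the linear (Wagner) matrix: changing from state `i` to
#' state `j` costs `|i - j|`, the natural choice for ranked characters such
#' as depth intervals.
#'
#' @param k number of states.
#' @param type `"unordered"` or `"ordered"`.
#' @return a `k x k` numeric cost matrix with zero diagonal.
#' @export
step_matrix <- function(k, type = c("unordered", "ordered")) {
  type <- match.arg(type)
  stopifnot(k >= 1)
  if (type == "unordered") {
    m <- matrix(1, k, k) - diag(k)
  } else {
    m <- abs(outer(seq_len(k), seq_len(k), "-"))
  }
  storage.mode(m) <- "double"
  m
}

.check_states <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips))
    stop("tip without state: ", paste(missing_tips, collapse = ", "))
  st <- states[tree$tip.label]
  if (anyNA(st)) stop("tip without state (NA)")
  as.integer(st)
}

.is_binary <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  all(tab[tab > 0] == 2L)
}

# Postorder edge matrix, 0-based, for the C Fitch kernel.
.edges_postorder0 <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  po$edge - 1L
}

#' Fitch parsimony length
#'
#' Minimum number of state changes on the tree under unit change costs
#' (unweighted parsimony), by Fitch's bottom-up set algorithm: intersect the
#' two child state sets, or take their union and add a step.  Binary trees
#' use a compiled kernel; polytomies delegate to the Sankoff recursion with
#' unit costs, which handles multifurcations exactly.
#'
#' @param tree a rooted `phylo` object (any rooting; the length is
#'   root-invariant).
#' @param states named integer vector of 1-based state indices, names = tip
#'   labels; every tip of the tree must have a non-missing state.
#' @param k number of states (default: largest observed index).
#' @return integer parsimony length.
#' @export
fitch_length <- function(tree, states, k = max(states)) {
  st <- .check_states(tree, states)
  n <- length(tree$tip.label)
  if (n < 2L) return(0L)
  if (!.is_binary(tree)) {
    return(as.integer(ancestral_parsimony(tree, states, costs = "unordered",
                                          k = k)$length))
  }
  fitch_count_edges(.edges_postorder0(tree), st - 1L, n, n + tree$Nnode)
}

#' Sankoff parsimony with MPR state sets
#'
#' Generalized (weighted) parsimony by the Sankoff dynamic programme.  The
#' bottom-up pass computes, for every node and state, the minimal cost of the
#' subtree; a top-down pass then recovers, for every node, the full set of
#' states attained by at least one globally minimal reconstruction (the MPR
#' set).  A node whose MPR set has more than one state is *equivocal* — ties
#' are kept as sets, never broken arbitrarily.  Polytomies are handled
#' natively (the recursion sums over all children).  Alongside the cost, the
#' minimal number of branches carrying a state change among all minimal-cost
#' reconstructions is tracked (for unit costs this equals the length).
#'
#' @inheritParams fitch_length
#' @param costs a `k x k` step matrix (see [step_matrix()]) or one of
#'   `"unordered"`, `"ordered"`.
#' @param character_name optional label carried into the result.
#' @return an object of class `ancestral_parsimony`: `length` (minimal total
#'   cost), `transitions` (minimal changed-branch count among minimal
#'   reconstructions), `mpr` (logical `node x k` matrix, `TRUE` when the
#'   state is in the node's MPR set), `equivocal` (logical per node),
#'   `tree`, `states`, `costs`, `character_name`.
#' @export
ancestral_parsimony <- function(tree, states, costs = "unordered",
                                k = max(states), character_name = NULL) {
  st <- .check_states(tree, states)
  if (is.character(costs)) costs <- step_matrix(k, costs)
  if (!is.matrix(costs) || nrow(costs) != k || ncol(costs) != k)
    stop("cost matrix must be ", k, " x ", k)
  if (any(diag(costs) != 0) || any(costs < 0))
    stop("cost matrix needs zero diagonal and nonnegative entries")
  if (any(st > k)) stop("state index exceeds k")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (ntip == 1L) {
    mpr <- matrix(FALSE, nn, k); mpr[cbind(seq_len(nn), c(st, st))] <- TRUE
    return(structure(list(length = 0, transitions = 0L, mpr = mpr,
                          equivocal = rep(FALSE, nn), tree = tree,
                          states = st, costs = costs,
                          character_name = character_name),
                     class = "ancestral_parsimony"))
  }
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  BIG <- .Machine$double.xmax / 8
  S <- matrix(BIG, nn, k)   # subtree cost given node state
  Tr <- matrix(BIG, nn, k)  # min changed branches among min-cost subtrees
  S[cbind(seq_len(ntip), st)] <- 0
  Tr[cbind(seq_len(ntip), st)] <- 0
  D <- 1 - diag(k)          # per-edge change indicator
  seen <- rep(FALSE, nn)
  contrib <- matrix(NA_real_, nrow(E), k)  # cost contribution of each edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    cand_cost <- costs + rep(S[ch, ], each = k)   # [a, b]
    cand_ch <- D + rep(Tr[ch, ], each = k)
    cc <- numeric(k); tt <- numeric(k)
    for (a in seq_len(k)) {
      m <- min(cand_cost[a, ])
      cc[a] <- m
      tt[a] <- min(cand_ch[a, cand_cost[a, ] <= m + 1e-9])
    }
    contrib[e, ] <- cc
    if (!seen[p]) {
      S[p, ] <- cc; Tr[p, ] <- tt; seen[p] <- TRUE
    } else {
      S[p, ] <- S[p, ] + cc; Tr[p, ] <- Tr[p, ] + tt
    }
  }
  root <- ntip + 1L
  L <- min(S[root, ])
  transitions <- min(Tr[root, S[root, ] <= L + 1e-9])
  # Top-down: U[v, s] = min cost of the rest of the tree given v has state s.
  U <- matrix(0, nn, k)
  for (e in rev(seq_len(nrow(E)))) {          # preorder
    p <- E[e, 1L]; ch <- E[e, 2L]
    Rp <- U[p, ] + S[p, ] - contrib[e, ]      # parent cost excluding this edge
    U[ch, ] <- apply(costs + Rp, 2L, min)     # min over parent state a
  }
  total <- S + U
  mpr <- total <= L + 1e-9
  equivocal <- rowSums(mpr) > 1L
  structure(list(length = L, transitions = as.integer(round(transitions)),
                 mpr = mpr, equivocal = equivocal, tree = tree,
                 states = setNames(st, tree$tip.label), costs = costs,
                 character_name = character_name),
            class = "ancestral_parsimony")
}

#' @export
print.ancestral_parsimony <- function(x, ...) {
  cat("Ancestral parsimony reconstruction")
  if (!is.null(x$character_name)) cat(" of '", x$character_name, "'", sep = "")
  cat("\n")
  cat("  tips:          ", length(x$tree$tip.label), "\n", sep = "")
  cat("  states:        ", ncol(x$mpr), "\n", sep = "")
  cat("  length (cost): ", x$length, "\n", sep = "")
  cat("  transitions:   ", x$transitions, "\n", sep = "")
  nint <- x$tree$Nnode
  neq <- sum(x$equivocal[-seq_len(length(x$tree$tip.label))])
  cat("  equivocal internal nodes: ", neq, " / ", nint, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ancestral_parsimony <- function(object, ...) {
  ntip <- length(object$tree$tip.label)
  nodes <- seq_len(ntip + object$tree$Nnode)
  df <- data.frame(
    node = nodes,
    is_tip = nodes <= ntip,
    label = c(object$tree$tip.label, rep(NA_character_, object$tree$Nnode)),
    mpr = vapply(nodes, function(v)
      paste(which(object$mpr[v, ]), collapse = "/"), character(1)),
    equivocal = object$equivocal,
    stringsAsFactors = FALSE)
  class(df) <- c("summary.ancestral_parsimony", class(df))
  df
}

#' Number of state transitions implied by a reconstruction
#'
#' For unit-cost (unweighted) matrices this equals the parsimony length —
#' each step is one transition.  For general step matrices it is the minimal
#' number of branches carrying a state change over all minimal-cost
#' reconstructions (a single `0 -> 2` change on one branch counts one
#' transition though it costs two under the ordered matrix).
#'
#' @param result an [ancestral_parsimony()] object.
#' @return integer transition count.
#' @export
count_transitions <- function(result) {
  stopifnot(inherits(result, "ancestral_parsimony"))
  result$transitions
}

#' Export a reconstruction as TSV
#'
#' One row per node: node id, tip label (empty for internal nodes), MPR state
#' set (`/`-separated 1-based indices) and the equivocal flag.
#'
#' @param result an [ancestral_parsimony()] object.
#' @param path output file.
#' @export
write_reconstruction_tsv <- function(result, path) {
  df <- summary(result)
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Export a reconstruction as annotated Newick
#'
#' Serializes the analysed tree with a comment tag `[&mpr=i/j]` after every
#' node carrying its MPR state set (and `*` when equivocal).  The comments
#' follow the common square-bracket metadata convention; strip them to
#' recover plain Newick.
#'
#' @param result an [ancestral_parsimony()] object.
#' @param path optional output file.
#' @return the annotated Newick string.
#' @export
write_annotated_newick <- function(result, path = NULL) {
  tree <- result$tree
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- tree$edge.length
  eidx <- seq_len(nrow(tree$edge))
  edge_of <- setNames(eidx, tree$edge[, 2L])
  tag <- function(v) {
    s <- paste(which(result$mpr[v, ]), collapse = "/")
    sprintf("[&mpr=%s%s]", s, if (result$equivocal[v]) "*" else "")
  }
  rec <- function(v) {
    core <- if (v <= ntip) {
      paste0(tree$tip.label[v], tag(v))
    } else {
      paste0("(", paste(vapply(kids[[as.character(v)]], rec, character(1)),
                        collapse = ","), ")", tag(v))
    }
    e <- edge_of[as.character(v)]
    if (!is.null(elen) && !is.na(e))
      core <- paste0(core, ":", format(elen[e], digits = 10))
    core
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (!is.null(path)) writeLines(s, path)
  s
}
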
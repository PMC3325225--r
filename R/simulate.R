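#' Simulate a Yule (pure-birth) tree
#'
#' Starting from two lineages at the root, each epoch with `k` lineages lasts
#' an exponential time with rate `k * birth`; a uniformly chosen lineage then
#' splits, until `n` lineages exist, after which one final exponential epoch
#' elapses.  The tree is ultrametric and the expected root height is
#' `sum_{k=2..n} 1 / (birth * k)`.
#'
#' @param n number of tips (`>= 2`).
#' @param birth speciation rate `lambda > 0`.
#' @param seed optional integer seed.
#' @param tip_labels optional labels (default `t1..tn`).
#' @return an ultrametric rooted binary `phylo` object.
#' @export
simulate_yule <- function(n, birth = 1, seed = NULL, tip_labels = NULL) {
  stopifnot(n >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n))
  stopifnot(length(tip_labels) == n)
  # grow on 0-based internal ids: tips 0..n-1, internals n..2n-2
  m <- 2L * n - 1L
  parent <- rep(-1L, m); left <- rep(-1L, m); right <- rep(-1L, m)
  blen <- numeric(m)
  root <- n  # first internal node
  left[root + 1L] <- 0L; right[root + 1L] <- 1L
  parent[0L + 1L] <- root; parent[1L + 1L] <- root
  active <- c(0L, 1L)
  next_int <- n + 1L
  next_tip <- 2L
  k <- 2L
  repeat {
    dt <- rexp(1, rate = k * birth)
    blen[active + 1L] <- blen[active + 1L] + dt
    if (k == n) break
    i <- sample.int(k, 1L)
    v <- active[i]
    u <- next_int; next_int <- next_int + 1L
    w <- next_tip; next_tip <- next_tip + 1L
    # v's pending branch becomes u's; v restarts as a child of u
    p <- parent[v + 1L]
    blen[u + 1L] <- blen[v + 1L]
    blen[v + 1L] <- 0
    parent[u + 1L] <- p
    if (p >= 0) { if (left[p + 1L] == v) left[p + 1L] <- u else right[p + 1L] <- u }
    if (v == root) root <- u
    left[u + 1L] <- v; right[u + 1L] <- w
    parent[v + 1L] <- u; parent[w + 1L] <- u
    active <- c(active, w)
    k <- k + 1L
  }
  # edge list (parent, child, length) -> phylo
  e0 <- matrix(0, 2L * n - 2L, 3L)
  r <- 0L
  for (v in which(parent >= 0L) - 1L) {
    r <- r + 1L
    e0[r, ] <- c(parent[v + 1L], v, blen[v + 1L])
  }
  .edges_to_phylo(e0, tip_labels)
}

#' Simulate a symmetric Mk character on a tree
#'
#' k-state symmetric continuous-time Markov evolution from a uniform root
#' state down to the tips.  `rate` is the instantaneous rate towards *each*
#' alternative state, so on a branch of length `t` the change probability
#' is `(k-1)/k * (1 - exp(-k * rate * t))` (for `k = 2`:
#' `(1 - exp(-2*rate*t)) / 2`).  Low rates on a fixed tree mean strong
#' phylogenetic signal.  True ancestral states are returned for recovery
#' studies.
#'
#' @param tree `phylo` object with branch lengths.
#' @param k number of states (`>= 2`).
#' @param rate per-target-state substitution rate (`>= 0`).
#' @param seed optional integer seed.
#' @return a list with `tip_states` (named integer vector), `node_states`
#'   (internal nodes, index `ntip+1 ..`), `root_state`, `k` and `rate`.
#' @export
evolve_mk <- function(tree, k, rate, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), k >= 2, rate >= 0)
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  state <- integer(nn)
  root <- ntip + 1L
  state[root] <- sample.int(k, 1L)
  pr <- ape::reorder.phylo(tree, "postorder")
  E <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE]  # preorder
  elen <- pr$edge.length[rev(seq_len(nrow(pr$edge)))]
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    pchange <- (k - 1) / k * (1 - exp(-k * rate * elen[e]))
    s <- state[p]
    if (runif(1) < pchange) {
      alt <- setdiff(seq_len(k), s)
      s <- alt[sample.int(length(alt), 1L)]  # not sample(): k=2 gives one alt
    }
    state[ch] <- s
  }
  list(tip_states = setNames(state[seq_len(ntip)], tree$tip.label),
       node_states = state[(ntip + 1L):nn],
       root_state = state[root], k = as.integer(k), rate = rate)
}

#' Simulate sequences under GTR+I+G on a tree
#'
#' Site-i.i.d. simulation: each site is invariable with probability `p_inv`
#' (identical across the tree, state drawn from the base frequencies),
#' otherwise it is assigned one of the discrete-gamma rate categories
#' uniformly and evolved with branch lengths scaled by the category rate.
#'
#' @param tree `phylo` object with branch lengths (expected substitutions per
#'   variable site).
#' @param model a [gtr_model()].
#' @param length number of sites (default 630, a typical partial COI
#'   fragment).
#' @param seed optional integer seed.
#' @return an alignment character matrix (rows = taxa).
#' @export
simulate_sequences <- function(tree, model, length = 630, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"),
            length >= 1)
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ntip <- Ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  rates <- if (model$ncat == 1L || is.infinite(model$alpha)) 1
           else discrete_gamma_rates(model$alpha, model$ncat)
  inv <- runif(length) < model$p_inv
  cat_of <- integer(length)
  cat_of[!inv] <- sample.int(base::length(rates), sum(!inv), replace = TRUE)
  root_state <- sample.int(4L, length, replace = TRUE, prob = model$base_freq)
  states <- matrix(0L, nn, length)
  states[ntip + 1L, ] <- root_state
  pr <- ape::reorder.phylo(tree, "postorder")
  E <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE]
  elen <- pr$edge.length[rev(seq_len(nrow(pr$edge)))]
  var_sites <- which(!inv)
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    states[ch, ] <- states[p, ]
    for (ci in seq_along(rates)) {
      sites <- var_sites[cat_of[var_sites] == ci]
      if (!base::length(sites)) next
      P <- gtr_pmatrix(model, rates[ci] * elen[e])
      ps <- states[p, sites]
      new <- integer(base::length(sites))
      for (b in 1:4) {
        idx <- which(ps == b)
        if (base::length(idx))
          new[idx] <- sample.int(4L, base::length(idx), replace = TRUE,
                                 prob = pmax(P[b, ], 0))
      }
      states[ch, sites] <- new
    }
  }
  aln <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], ntip, length,
                dimnames = list(tree$tip.label, NULL))
  aln
}

#' Study-scale simulation configuration
#'
#' Defaults emulate the shape of a family-wide COI barcoding data set: 87
#' taxa on a Yule tree, a 630-site alignment under GTR+I+G with the
#' literature-typical COI parameters `p_inv = 0.39` and gamma shape `0.54`,
#' one 13-state ordered-capable depth character and one 4-state habitat
#' character evolved by Mk on the same tree, with the character analysis
#' restricted to a 53-taxon ingroup subset.
#'
#' @param n_taxa tips on the simulated tree.
#' @param n_character_taxa taxa carrying character data (ingroup subset;
#'   default 53, capped at `n_taxa`).
#' @param birth Yule speciation rate (tree time units).
#' @param seq_length alignment columns.
#' @param seq_scale multiplier taking tree branch lengths into expected
#'   substitutions per variable site for sequence simulation.
#' @param model a [gtr_model()] for the sequences.
#' @param depth_states,habitat_states state counts of the two characters.
#' @param mk_rate Mk substitution rate of the characters (the signal knob:
#'   low rate = strong phylogenetic signal).
#' @param seed integer seed (mandatory: the bundle must be reproducible).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 87, n_character_taxa = min(53, n_taxa),
                              birth = 1,
                              seq_length = 630, seq_scale = 0.05,
                              model = gtr_model(
                                rates = c(1, 4, 1, 1, 4, 1),
                                base_freq = c(0.28, 0.2, 0.2, 0.32),
                                p_inv = 0.39, alpha = 0.54, ncat = 4),
                              depth_states = 13, habitat_states = 4,
                              mk_rate = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_taxa >= 2, n_character_taxa >= 3, n_character_taxa <= n_taxa,
            birth > 0, seq_length >= 1, seq_scale > 0,
            depth_states >= 2, habitat_states >= 2, mk_rate >= 0)
  structure(list(n_taxa = n_taxa, n_character_taxa = n_character_taxa,
                 birth = birth, seq_length = seq_length,
                 seq_scale = seq_scale, model = model,
                 depth_states = as.integer(depth_states),
                 habitat_states = as.integer(habitat_states),
                 mk_rate = mk_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a complete synthetic study bundle
#'
#' Simulates a Yule tree, a GTR+I+G alignment, and depth + habitat characters
#' with known ground truth, then writes `tree.nwk`, `alignment.fasta`,
#' `characters.tsv` (taxon, max_depth_m, habitat for the character-bearing
#' subset), `characters.nex` and `truth.json` (generating parameters, true
#' tree, true ancestral states) under one directory.  Byte-identical outputs
#' under the same seed.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the simulated objects (`tree`, `alignment`,
#'   `character_matrix`, `truth`) and the file paths.
#' @export
make_fixture_study <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  tree <- simulate_yule(config$n_taxa, config$birth)
  seq_tree <- tree
  seq_tree$edge.length <- seq_tree$edge.length * config$seq_scale
  aln <- simulate_sequences(seq_tree, config$model, config$seq_length)
  char_taxa <- sort(sample(tree$tip.label, config$n_character_taxa))
  char_tree <- ape::drop.tip(tree, setdiff(tree$tip.label, char_taxa))
  depth <- evolve_mk(char_tree, config$depth_states, config$mk_rate)
  habitat <- evolve_mk(char_tree, config$habitat_states, config$mk_rate)
  binning <- depth_binning()
  # representative metre value inside each simulated depth interval
  lower <- c(0, binning$edges)
  upper <- c(binning$edges, 8000)
  mid <- (lower + upper) / 2
  nb <- length(binning$labels)
  depth_idx <- pmin(depth$tip_states, nb)
  hab_idx <- ((habitat$tip_states - 1L) %% 4L) + 1L
  df <- data.frame(taxon = names(depth$tip_states),
                   max_depth_m = mid[depth_idx],
                   habitat = habitat_levels()[hab_idx],
                   stringsAsFactors = FALSE)
  cm <- character_matrix(df$taxon, list(
    depth = list(states = unname(depth_idx), alphabet = binning$labels,
                 ordered = FALSE),
    habitat = list(states = unname(hab_idx),
                   alphabet = habitat_levels(), ordered = FALSE)))
  paths <- list(tree = file.path(dir, "tree.nwk"),
                alignment = file.path(dir, "alignment.fasta"),
                characters_tsv = file.path(dir, "characters.tsv"),
                characters_nex = file.path(dir, "characters.nex"),
                truth = file.path(dir, "truth.json"))
  write_newick(tree, paths$tree)
  write_fasta_alignment(aln, paths$alignment)
  write.table(df, paths$characters_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_nexus_characters(cm, paths$characters_nex)
  truth <- list(seed = config$seed,
                n_taxa = config$n_taxa,
                n_character_taxa = config$n_character_taxa,
                birth = config$birth,
                seq_length = config$seq_length,
                seq_scale = config$seq_scale,
                mk_rate = config$mk_rate,
                gtr = list(rates = config$model$rates,
                           base_freq = config$model$base_freq,
                           p_inv = config$model$p_inv,
                           alpha = config$model$alpha,
                           ncat = config$model$ncat),
                tree_newick = write_newick(tree),
                character_tree_newick = write_newick(char_tree),
                depth_true_root = depth$root_state,
                depth_true_node_states = depth$node_states,
                habitat_true_root = habitat$root_state,
                habitat_true_node_states = habitat$node_states)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paths$truth)
  invisible(list(tree = tree, alignment = aln, character_matrix = cm,
                 character_tree = char_tree,
                 depth = depth, habitat = habitat, truth = truth,
                 paths = paths))
}
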
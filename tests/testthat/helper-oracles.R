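# Independent oracles and small generators used across the test files.

# Exhaustive parsimony: enumerate every assignment of states to internal
# nodes; return the minimal total cost, the minimal changed-branch count
# among minimal-cost assignments, and per-node MPR sets (states attained by
# at least one minimal assignment).  Deliberately brute force.
brute_force_parsimony <- function(tree, states, costs) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  k <- ncol(costs)
  st <- as.integer(states[tree$tip.label])
  E <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  full <- cbind(matrix(rep(st, each = nrow(grid)), nrow(grid)), grid)
  cost <- numeric(nrow(grid))
  changes <- integer(nrow(grid))
  for (e in seq_len(nrow(E))) {
    a <- full[, E[e, 1]]
    b <- full[, E[e, 2]]
    cost <- cost + costs[cbind(a, b)]
    changes <- changes + (a != b)
  }
  L <- min(cost)
  hit <- cost <= L + 1e-9
  mpr <- matrix(FALSE, ntip + nint, k)
  for (v in seq_len(ntip + nint)) mpr[cbind(v, unique(full[hit, v]))] <- TRUE
  list(length = L, transitions = min(changes[hit]), mpr = mpr)
}

# Random rooted binary tree over n tips with random states, for fuzzing.
random_instance <- function(n, k, lengths = FALSE) {
  tr <- phylochar::random_topology(paste0("t", seq_len(n)))
  if (lengths) tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  st <- setNames(sample.int(k, n, replace = TRUE), tr$tip.label)
  # ensure every instance uses at least one state (k may exceed usage)
  list(tree = tr, states = st)
}

# Canonical key of a rooted topology: recursively sorted label nesting.
topology_key <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    parts <- sort(vapply(kids[[as.character(v)]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(ntip + 1L)
}

# Closed-form JC69 2-taxon log-likelihood at path distance d:
# per-site likelihood is pi_x * P_{x->y}(d) with the textbook
# 1/4 + 3/4 exp(-4d/3) / 1/4 - 1/4 exp(-4d/3) transition probabilities.
jc_pair_loglik <- function(aln, d) {
  same <- aln[1, ] == aln[2, ]
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * d / 3)
  p_diff_specific <- 1 / 4 - 1 / 4 * exp(-4 * d / 3)
  sum(log(1 / 4 * ifelse(same, p_same, p_diff_specific)))
}

# Brute-force GTR+I+G likelihood: explicit sum over internal-node states and
# rate categories, built only from the model's P matrices.
brute_force_loglik <- function(tree, aln, model) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  E <- tree$edge
  elen <- tree$edge.length
  pi4 <- model$base_freq
  rates <- if (model$ncat == 1L || is.infinite(model$alpha)) 1
           else phylochar::discrete_gamma_rates(model$alpha, model$ncat)
  base_idx <- c(A = 1, C = 2, G = 3, T = 4)
  sub <- aln[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:4), nint)))
  ll <- 0
  for (s in seq_len(ncol(sub))) {
    obs <- base_idx[sub[, s]]
    lik_var <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(E)), function(e)
        phylochar:::gtr_pmatrix(model, r * elen[e]))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        full <- c(obs, grid[g, ])
        if (anyNA(obs)) next
        term <- pi4[full[ntip + 1L]]
        for (e in seq_len(nrow(E)))
          term <- term * Ps[[e]][full[E[e, 1]], full[E[e, 2]]]
        tot <- tot + term
      }
      lik_var <- lik_var + tot / length(rates)
    }
    lik_inv <- if (length(unique(obs)) == 1L) pi4[obs[1]] else 0
    ll <- ll + log(model$p_inv * lik_inv + (1 - model$p_inv) * lik_var)
  }
  ll
}
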
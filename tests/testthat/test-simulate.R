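test_that("Yule trees are ultrametric with the right size and height law", {
  t2 <- simulate_yule(2, birth = 1, seed = 1)
  depths <- ape::node.depth.edgelength(t2)
  expect_equal(depths[1], depths[2], tolerance = 1e-12)
  for (n in c(5, 16)) {
    tr <- simulate_yule(n, birth = 2, seed = n)
    expect_equal(length(tr$tip.label), n)
    expect_equal(tr$Nnode, n - 1L)
    d <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(diff(range(d)), 1e-9)  # ultrametric
  }
  # mean root height over replicates matches sum_{k=2..n} 1/(lambda k)
  set.seed(321)
  n <- 8; lam <- 1.5; reps <- 2000
  h <- replicate(reps, {
    tr <- simulate_yule(n, birth = lam)
    ape::node.depth.edgelength(tr)[1]
  })
  expected <- sum(1 / (lam * (2:n)))
  sd_h <- sqrt(sum(1 / (lam * (2:n))^2))  # sum of independent exponentials
  expect_lt(abs(mean(h) - expected), 3 * sd_h / sqrt(reps))
  expect_error(simulate_yule(1), "n >= 2")
})

test_that("Mk simulation follows the closed-form change probability", {
  tr <- parse_newick("(A:0.7,B:0.7);")
  # two-state chain on the two root-to-tip branches: each branch changes
  # with probability (1 - exp(-2 r t)) / 2
  set.seed(12)
  reps <- 4000
  r <- 0.9; t_br <- 0.7
  diff_frac <- mean(replicate(reps, {
    s <- evolve_mk(tr, k = 2, rate = r)
    s$tip_states[["A"]] != s$root_state
  }))
  p <- (1 - exp(-2 * r * t_br)) / 2
  expect_lt(abs(diff_frac - p), 3 * sqrt(p * (1 - p) / reps))
  # rate 0: every tip inherits the root state; parsimony length 0
  big <- simulate_yule(12, seed = 3)
  s0 <- evolve_mk(big, k = 4, rate = 0, seed = 4)
  expect_true(all(s0$tip_states == s0$root_state))
  expect_equal(fitch_length(big, s0$tip_states), 0L)
  expect_error(evolve_mk(random_topology(letters[1:4], seed = 1), 2, 1),
               "branch length")
})

test_that("saturated Mk approaches the shuffle null and low rate stays below it", {
  set.seed(55)
  tr <- simulate_yule(24, seed = 56)
  hot <- evolve_mk(tr, k = 4, rate = 50)
  obs_hot <- fitch_length(tr, hot$tip_states)
  null <- signal_test(tr, hot$tip_states, N = 299, seed = 57,
                      method = "shuffle_tips")
  # saturated states are exchangeable across tips: observed within the null
  expect_gt(null$p_value, 0.01)
  cold <- evolve_mk(tr, k = 4, rate = 0.05)
  if (length(unique(cold$tip_states)) > 1) {
    ts_cold <- signal_test(tr, cold$tip_states, N = 299, seed = 58)
    expect_lte(ts_cold$observed, ts_cold$null_mean)
  }
  expect_lte(obs_hot, 23)
})

test_that("sequence simulation honours degenerate regimes and expected divergence", {
  star0 <- ape::rtree(5)
  star0$edge.length <- rep(0, nrow(star0$edge))
  m <- gtr_model(p_inv = 0, alpha = Inf, ncat = 1)
  aln0 <- simulate_sequences(star0, m, length = 50, seed = 6)
  expect_true(all(apply(aln0, 2, function(col) length(unique(col)) == 1)))
  m_inv <- gtr_model(p_inv = 1 - 1e-12, alpha = 0.5)
  expect_error(gtr_model(p_inv = 1), "p_inv")
  # p_inv ~ 1: essentially no variable sites
  aln1 <- simulate_sequences(ape::rtree(4), m_inv, length = 100, seed = 7)
  expect_true(all(apply(aln1, 2, function(col) length(unique(col)) == 1)))
  # long pair: observed p-distance matches the model expectation at 50 kb
  mod <- gtr_model(rates = c(1, 4, 1, 1, 4, 1),
                   base_freq = c(0.28, 0.2, 0.2, 0.32),
                   p_inv = 0.39, alpha = 0.54, ncat = 4)
  d <- 0.4
  tr <- parse_newick(sprintf("(A:%f,B:%f);", d / 2, d / 2))
  L <- 50000
  aln <- simulate_sequences(tr, mod, length = L, seed = 9)
  rates <- discrete_gamma_rates(0.54, 4)
  exp_p <- (1 - mod$p_inv) * mean(vapply(rates, function(r) {
    P <- pracma::expm(mod$Q * r * d)
    1 - sum(mod$base_freq * diag(P))
  }, numeric(1)))
  obs_p <- p_distance(aln, "A", "B")
  expect_lt(abs(obs_p - exp_p), 3 * sqrt(exp_p * (1 - exp_p) / L))
})

test_that("the study bundle has the right shape and is byte-reproducible", {
  cfg <- simulation_config(n_taxa = 30, n_character_taxa = 20,
                           seq_length = 120, seed = 77)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  b1 <- make_fixture_study(cfg, d1)
  b2 <- make_fixture_study(cfg, d2)
  expect_equal(length(b1$tree$tip.label), 30L)
  expect_equal(ncol(b1$alignment), 120L)
  expect_equal(length(b1$character_matrix$taxa), 20L)
  expect_length(b1$character_matrix$characters$depth$alphabet, 13L)
  expect_length(b1$character_matrix$characters$habitat$alphabet, 4L)
  for (f in c("tree.nwk", "alignment.fasta", "characters.tsv",
              "characters.nex", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # truth states agree with the returned simulation objects
  truth <- jsonlite::fromJSON(file.path(d1, "truth.json"))
  expect_equal(truth$depth_true_root, b1$depth$root_state)
  expect_equal(truth$habitat_true_node_states, b1$habitat$node_states)
  # the written table reloads into the very same character states
  cm <- read_character_table(file.path(d1, "characters.tsv"))
  expect_equal(character_states(cm, "depth"),
               character_states(b1$character_matrix, "depth"))
  expect_equal(character_states(cm, "habitat"),
               character_states(b1$character_matrix, "habitat"))
  expect_error(simulation_config(n_taxa = 10, n_character_taxa = 8, seed = 1,
                                 depth_states = 1), "depth_states")
})

test_that("median signal p-value increases with the Mk rate", {
  set.seed(404)
  meds <- vapply(c(0.05, 0.5, 5), function(rate) {
    p <- replicate(60, {
      tr <- simulate_yule(32)
      st <- evolve_mk(tr, k = 4, rate = rate)$tip_states
      if (length(unique(st)) == 1) 1 else
        signal_test(tr, st, N = 99)$p_value
    })
    median(p)
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
  expect_lt(meds[1], 0.05)
})
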
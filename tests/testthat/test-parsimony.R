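test_that("Fitch length matches forced small cases", {
  t1 <- parse_newick("((A,B),(C,D));")
  st <- setNames(c(1L, 1L, 2L, 2L), c("A", "B", "C", "D"))
  expect_equal(fitch_length(t1, st), 1L)
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(fitch_length(t2, st), 2L)
  expect_equal(fitch_length(t1, setNames(rep(1L, 4), c("A", "B", "C", "D"))),
               0L)
  expect_error(fitch_length(t1, st[-1]), "tip without state")
})

test_that("Sankoff agrees with the exhaustive oracle on length, MPR sets and transitions", {
  set.seed(2024)
  types <- c("unordered", "ordered")
  for (i in 1:120) {
    inst <- random_instance(n = sample(4:7, 1), k = sample(2:4, 1))
    k <- max(inst$states)
    costs <- step_matrix(k, sample(types, 1))
    rec <- ancestral_parsimony(inst$tree, inst$states, costs = costs, k = k)
    bf <- brute_force_parsimony(inst$tree, inst$states, costs)
    expect_equal(rec$length, bf$length)
    expect_equal(rec$transitions, bf$transitions)
    expect_equal(rec$mpr, bf$mpr)
  }
})

test_that("equivocal flags and tip MPR sets follow their definitions", {
  t2 <- parse_newick("((A,C),(B,D));")
  st <- setNames(c(1L, 1L, 2L, 2L), c("A", "B", "C", "D"))
  rec <- ancestral_parsimony(t2, st)
  # root MPR set {1, 2}: the root is equivocal
  expect_equal(which(rec$mpr[5, ]), c(1L, 2L))
  expect_true(rec$equivocal[5])
  # every tip keeps its observed singleton
  for (i in 1:4) expect_equal(which(rec$mpr[i, ]), unname(st[t2$tip.label[i]]))
  expect_equal(rec$equivocal, rowSums(rec$mpr) > 1)
})

test_that("ordered costs: one 0->2 jump costs 2 but is a single transition", {
  tr <- parse_newick("((A,B),(C,D));")
  st <- setNames(c(1L, 1L, 3L, 3L), c("A", "B", "C", "D"))
  rec <- ancestral_parsimony(tr, st, costs = "ordered", k = 3)
  expect_equal(rec$length, 2)
  expect_equal(count_transitions(rec), 1L)
  unit <- ancestral_parsimony(tr, st, costs = "unordered", k = 3)
  expect_equal(count_transitions(unit), as.integer(unit$length))
})

test_that("parsimony length is invariant to rerooting for symmetric costs", {
  set.seed(77)
  for (i in 1:10) {
    inst <- random_instance(n = 8, k = 3, lengths = TRUE)
    k <- max(inst$states)
    base_len <- ancestral_parsimony(inst$tree, inst$states,
                                    costs = "ordered", k = k)$length
    for (e in seq_len(nrow(inst$tree$edge))) {
      rr <- reroot_edge(inst$tree, e)
      expect_equal(ancestral_parsimony(rr, inst$states, costs = "ordered",
                                       k = k)$length, base_len)
    }
  }
})

test_that("unit-cost length bounds and tip-addition monotonicity hold", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    inst <- random_instance(n, k = sample(2:5, 1))
    len <- fitch_length(inst$tree, inst$states)
    expect_lte(len, n - 1)
    expect_gte(len, length(unique(inst$states)) - 1)
    # drop a random tip: length cannot increase
    drop <- sample(inst$tree$tip.label, 1)
    sub <- ape::drop.tip(inst$tree, drop)
    expect_lte(fitch_length(sub, inst$states[sub$tip.label]), len)
  }
})

test_that("MPR clamping: states in the set achieve the optimum, others exceed it", {
  # force node v to state s by attaching a zero-cost constraint through
  # brute-force filtering of assignments
  set.seed(15)
  for (i in 1:25) {
    inst <- random_instance(n = sample(4:6, 1), k = 3)
    k <- max(inst$states)
    costs <- step_matrix(k, "unordered")
    rec <- ancestral_parsimony(inst$tree, inst$states, costs = costs, k = k)
    ntip <- length(inst$tree$tip.label)
    E <- inst$tree$edge
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), inst$tree$Nnode)))
    full <- cbind(matrix(rep(as.integer(inst$states[inst$tree$tip.label]),
                             each = nrow(grid)), nrow(grid)), grid)
    cost <- numeric(nrow(grid))
    for (e in seq_len(nrow(E)))
      cost <- cost + costs[cbind(full[, E[e, 1]], full[, E[e, 2]])]
    for (v in (ntip + 1):(ntip + inst$tree$Nnode)) {
      for (s in seq_len(k)) {
        best_with_s <- min(cost[full[, v] == s])
        if (rec$mpr[v, s]) expect_equal(best_with_s, rec$length)
        else expect_gt(best_with_s, rec$length)
      }
    }
  }
})

test_that("polytomies are handled exactly via the Sankoff recursion", {
  tr <- parse_newick("((A,B,C),(D,E));")
  st <- setNames(c(1L, 1L, 2L, 2L, 2L), c("A", "B", "C", "D", "E"))
  bf <- brute_force_parsimony(tr, st, step_matrix(2, "unordered"))
  expect_equal(fitch_length(tr, st), as.integer(bf$length))
  rec <- ancestral_parsimony(tr, st)
  expect_equal(rec$mpr, bf$mpr)
})

test_that("reconstruction exports are readable and carry MPR sets", {
  tr <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  st <- setNames(c(1L, 1L, 2L, 2L), c("A", "B", "C", "D"))
  rec <- ancestral_parsimony(tr, st, character_name = "toy")
  tsv <- tempfile(fileext = ".tsv")
  write_reconstruction_tsv(rec, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 7L)
  expect_equal(df$mpr[df$node == 5], "1/2")
  expect_true(df$equivocal[df$node == 5])
  s <- write_annotated_newick(rec)
  expect_match(s, "\\[&mpr=1/2\\*\\]")
  expect_match(s, "^\\(")
})
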
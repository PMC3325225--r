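#' Null distribution of parsimony lengths and phylogenetic-signal test
#'
#' Tests whether a discrete character is more conserved on a phylogeny than
#' expected by chance: the observed parsimony length is compared against the
#' lengths obtained on `N` randomized trees.  Two null models are available:
#'
#' * `"random_topology"` (default): each replicate draws a new topology
#'   uniformly from all labelled rooted binary topologies on the same tip set
#'   ([random_topology()]), the convention of classic character-tracing
#'   software ("equiprobable trees");
#' * `"shuffle_tips"`: the observed topology is kept and the tip labels are
#'   permuted ([shuffle_tips()]).
#'
#' Fewer observed steps than the null indicates phylogenetic signal.  The
#' one-tailed p-value uses the add-one rank rule
#' `p = (1 + #\{null <= observed\}) / (N + 1)`, so it is never exactly zero;
#' a descriptive z-like score `(observed - null mean) / null sd` is also
#' reported, mirroring the traditional comparison of the observed length with
#' the null mean.
#'
#' Unit-cost binary-tree nulls run through a compiled Fitch kernel; general
#' step matrices or multifurcating observed trees (shuffle method) fall back
#' to the Sankoff engine.
#'
#' @param tree a rooted `phylo` object with at least 3 tips.
#' @param states named integer state vector (names = tip labels).
#' @param costs step matrix or `"unordered"`/`"ordered"` (see
#'   [step_matrix()]).
#' @param N number of randomizations (default 1000).
#' @param method `"random_topology"` or `"shuffle_tips"`.
#' @param seed integer seed; required for reproducible nulls.
#' @param character_name optional label.
#' @return an object of class `signal_test` with fields `observed`,
#'   `null_lengths`, `null_mean`, `null_sd`, `p_value`, `z`, `N`, `method`,
#'   `seed`, `character_name`.
#' @export
signal_test <- function(tree, states, costs = "unordered", N = 1000,
                        method = c("random_topology", "shuffle_tips"),
                        seed = NULL, character_name = NULL) {
  method <- match.arg(method)
  stopifnot(N >= 1)
  st <- .check_states(tree, states)
  n <- length(tree$tip.label)
  if (n < 3L) stop("fewer than 3 tips: null distribution is degenerate")
  k <- max(st)
  if (is.character(costs)) costs <- step_matrix(k, costs)
  unit <- all(costs == step_matrix(nrow(costs), "unordered"))
  observed <- if (unit) fitch_length(tree, setNames(st, tree$tip.label),
                                     k = nrow(costs))
              else ancestral_parsimony(tree, setNames(st, tree$tip.label),
                                       costs = costs, k = nrow(costs))$length
  if (!is.null(seed)) set.seed(seed)
  if (unit && (method == "random_topology" || .is_binary(tree))) {
    null_lengths <- if (method == "random_topology") {
      null_lengths_topology(st - 1L, as.integer(N))
    } else {
      null_lengths_shuffle(.edges_postorder0(tree), st - 1L, n,
                           n + tree$Nnode, as.integer(N))
    }
    null_lengths <- as.numeric(null_lengths)
  } else {
    null_lengths <- vapply(seq_len(N), function(i) {
      rt <- if (method == "random_topology") {
        rt0 <- random_topology(tree$tip.label)
        rt0
      } else {
        shuffle_tips(tree)
      }
      ancestral_parsimony(rt, setNames(st, tree$tip.label), costs = costs,
                          k = nrow(costs))$length
    }, numeric(1))
  }
  null_mean <- mean(null_lengths)
  null_sd <- sd(null_lengths)
  p <- (1 + sum(null_lengths <= observed)) / (N + 1)
  z <- if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd else NA_real_
  structure(list(observed = as.numeric(observed),
                 null_lengths = null_lengths,
                 null_mean = null_mean, null_sd = null_sd,
                 p_value = p, z = z, N = as.integer(N), method = method,
                 seed = seed, character_name = character_name),
            class = "signal_test")
}

#' One-tailed p-value of a signal test
#'
#' `p = (1 + #\{null lengths <= observed\}) / (N + 1)`; small values mean the
#' character needs fewer steps on the observed tree than on random trees,
#' i.e. phylogenetic signal.
#'
#' @param null a [signal_test()] object.
#' @return the p-value in `(0, 1]`.
#' @export
signal_pvalue <- function(null) {
  stopifnot(inherits(null, "signal_test"))
  null$p_value
}

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal randomization test")
  if (!is.null(x$character_name)) cat(" for '", x$character_name, "'", sep = "")
  cat("\n")
  cat(sprintf("  observed steps: %g\n", x$observed))
  cat(sprintf("  null mean (sd): %.3f (%.3f)  [N = %d, method = %s]\n",
              x$null_mean, x$null_sd, x$N, x$method))
  if (!is.na(x$z)) cat(sprintf("  z score:        %.3f\n", x$z))
  cat(sprintf("  one-tailed p:   %.4g\n", x$p_value))
  invisible(x)
}

#' @export
plot.signal_test <- function(x, ...) {
  graphics::hist(x$null_lengths,
                 main = "Null distribution of parsimony lengths",
                 xlab = "steps on randomized trees",
                 xlim = range(c(x$null_lengths, x$observed)), ...)
  graphics::abline(v = x$observed, col = 2, lwd = 2)
  invisible(x)
}

#' Run the full signal test for one character of a matrix on a tree
#'
#' Reconciles the tree with the character matrix, prunes both to their shared
#' taxa (taxa with a missing state for the chosen character are dropped too),
#' runs [ancestral_parsimony()] and [signal_test()], and returns a structured
#' report.
#'
#' @param tree a rooted `phylo` object.
#' @param cm a [character_matrix()].
#' @param character name of the character to test.
#' @param costs,N,method,seed passed to [signal_test()]; the depth/habitat
#'   defaults are unweighted parsimony and 1000 random topologies.
#' @return a list of class `character_test_report`: the `signal_test` object
#'   (`test`), the reconstruction on the pruned tree (`reconstruction`),
#'   `pruned_taxa` (dropped tip labels) and the resolved configuration.
#' @export
run_character_test <- function(tree, cm, character, costs = "unordered",
                               N = 1000, method = "random_topology",
                               seed = NULL) {
  v <- validate_against_tree(cm, tree)
  st <- character_states(cm, character)         # missing dropped here
  usable <- intersect(v$shared, names(st))
  dropped <- setdiff(tree$tip.label, usable)
  if (length(usable) < 3L)
    stop("fewer than 3 usable taxa for character '", character, "'")
  sub <- if (length(dropped)) ape::drop.tip(tree, dropped) else tree
  k <- length(cm$characters[[character]]$alphabet)
  rec <- ancestral_parsimony(sub, st[sub$tip.label],
                             costs = if (is.character(costs))
                               step_matrix(k, costs) else costs,
                             k = k, character_name = character)
  ts <- signal_test(sub, st[sub$tip.label],
                    costs = if (is.character(costs))
                      step_matrix(k, costs) else costs,
                    N = N, method = method, seed = seed,
                    character_name = character)
  structure(list(test = ts, reconstruction = rec, pruned_taxa = dropped,
                 character = character, N = as.integer(N), method = method,
                 seed = seed),
            class = "character_test_report")
}

#' @export
print.character_test_report <- function(x, ...) {
  print(x$test)
  if (length(x$pruned_taxa))
    cat("  pruned taxa:    ", length(x$pruned_taxa), "\n")
  invisible(x)
}

#' Serialize a character test report as JSON
#'
#' @param report a [run_character_test()] report.
#' @param path optional output file.
#' @param null_lengths_tsv optional path: dump the null lengths as a
#'   one-column TSV for plotting.
#' @return the JSON string, invisibly when written to file.
#' @export
report_to_json <- function(report, path = NULL, null_lengths_tsv = NULL) {
  stopifnot(inherits(report, "character_test_report"))
  ts <- report$test
  obj <- list(character = report$character,
              observed_steps = ts$observed,
              null_mean = ts$null_mean,
              null_sd = ts$null_sd,
              z = ts$z,
              p_value = ts$p_value,
              N = ts$N,
              method = ts$method,
              seed = if (is.null(ts$seed)) NA else ts$seed,
              n_tips = length(report$reconstruction$tree$tip.label),
              pruned_taxa = report$pruned_taxa,
              transitions = report$reconstruction$transitions)
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(null_lengths_tsv))
    write.table(data.frame(null_length = ts$null_lengths), null_lengths_tsv,
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
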
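# Pipeline-level wrappers: each mirrors a shell subcommand (trace, test,
# monophyly, divergence, likelihood, nj, simulate).  Error conditions carry a
# class so the CLI script can map them onto exit codes (input/parse = 2,
# validation = 3, internal = 4).

.input_error <- function(...) {
  stop(structure(class = c("phylochar_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.read_tree_file <- function(path) {
  if (!file.exists(path)) .input_error("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tryCatch(parse_newick(txt), error = function(e)
    .input_error("failed to parse tree '", path, "': ", conditionMessage(e)))
}

#' Trace a character onto a tree (pipeline)
#'
#' Validate, prune, reconstruct ancestral states by parsimony, and export a
#' per-node TSV plus an annotated Newick.  The file-level equivalent of
#' [ancestral_parsimony()].
#'
#' @param tree_file Newick file.
#' @param table_file TSV with `taxon`, `max_depth_m`, `habitat` columns.
#' @param character `"depth"` or `"habitat"` (or any character in the table).
#' @param out_dir output directory for `trace_<character>.tsv` and
#'   `trace_<character>.nwk`.
#' @param costs `"unordered"` (default) or `"ordered"`.
#' @param binning a [depth_binning()].
#' @return the [ancestral_parsimony()] object, invisibly.
#' @export
trace_character <- function(tree_file, table_file, character,
                            out_dir = ".", costs = "unordered",
                            binning = depth_binning()) {
  tree <- .read_tree_file(tree_file)
  if (!file.exists(table_file))
    .input_error("character table not found: ", table_file)
  cm <- read_character_table(table_file, binning = binning)
  if (!character %in% names(cm$characters))
    .input_error("no such character: ", character)
  if (!.is_binary(tree))
    message("note: input tree contains polytomies; using the Sankoff path")
  v <- validate_against_tree(cm, tree)
  st <- character_states(cm, character)
  usable <- intersect(v$shared, names(st))
  sub <- ape::drop.tip(tree, setdiff(tree$tip.label, usable))
  k <- length(cm$characters[[character]]$alphabet)
  rec <- ancestral_parsimony(sub, st[sub$tip.label], costs = costs, k = k,
                             character_name = character)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_reconstruction_tsv(rec, file.path(out_dir,
                                          paste0("trace_", character, ".tsv")))
  write_annotated_newick(rec, file.path(out_dir,
                                        paste0("trace_", character, ".nwk")))
  invisible(rec)
}

#' Signal test from files (pipeline)
#'
#' File-level wrapper over [run_character_test()]; writes a JSON report and
#' returns it.  Deterministic per seed.
#'
#' @inheritParams trace_character
#' @param N randomizations (default 1000).
#' @param method `"random_topology"` or `"shuffle_tips"`.
#' @param seed integer seed (required).
#' @param out_json output JSON path (default `test_<character>.json` in
#'   `out_dir`).
#' @return the [run_character_test()] report, invisibly.
#' @export
test_character <- function(tree_file, table_file, character, seed,
                           N = 1000, method = "random_topology",
                           out_dir = ".", out_json = NULL,
                           binning = depth_binning()) {
  if (missing(seed)) .input_error("seed is required for test_character")
  tree <- .read_tree_file(tree_file)
  cm <- read_character_table(table_file, binning = binning)
  if (!character %in% names(cm$characters))
    .input_error("no such character: ", character)
  rep <- run_character_test(tree, cm, character, N = N, method = method,
                            seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(out_json))
    out_json <- file.path(out_dir, paste0("test_", character, ".json"))
  report_to_json(rep, out_json)
  invisible(rep)
}

#' Monophyly assessment from files (pipeline)
#'
#' @param tree_file Newick file.
#' @param groups_file TSV with columns `group` and `taxon` (one member per
#'   row).
#' @return data.frame as from [monophyly_table()].
#' @export
monophyly_from_files <- function(tree_file, groups_file) {
  tree <- .read_tree_file(tree_file)
  if (!file.exists(groups_file))
    .input_error("groups file not found: ", groups_file)
  df <- read.delim(groups_file, stringsAsFactors = FALSE)
  if (!all(c("group", "taxon") %in% names(df)))
    .input_error("groups file needs columns: group, taxon")
  monophyly_table(tree, split(df$taxon, df$group))
}

#' Simulate a study bundle (pipeline)
#'
#' @param dir output directory.
#' @param seed integer seed (required).
#' @param ... overrides passed to [simulation_config()].
#' @return invisibly, the [make_fixture_study()] bundle.
#' @export
simulate_study <- function(dir, seed, ...) {
  if (missing(seed)) .input_error("seed is required for simulate_study")
  cfg <- tryCatch(simulation_config(seed = seed, ...), error = function(e)
    .input_error("invalid simulation config: ", conditionMessage(e)))
  make_fixture_study(cfg, dir)
}
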
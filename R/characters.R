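#' Depth-interval binning scheme
#'
#' Discretizes maximum occurrence depth (metres) into ordered intervals.
#' The default edges partition the water column into 13 intervals — a
#' sublittoral band up to the shelf break followed by bathyal and abyssal
#' slices — `[0,200) [200,500) ... [5000,6000) [6000,Inf)`.  The scheme is
#' fully configurable; all analyses downstream are agnostic to the exact
#' boundaries.
#'
#' @param edges strictly increasing positive depth boundaries in metres;
#'   `length(edges) + 1` intervals result.
#' @return an object of class `depth_binning` with fields `edges` and
#'   `labels`.
#' @export
depth_binning <- function(edges = c(200, 500, 1000, 1500, 2000, 2500, 3000,
                                    3500, 4000, 4500, 5000, 6000)) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(edges <= 0)) stop("edges must be positive depths")
  lower <- c(0, edges)
  upper <- c(edges, Inf)
  labels <- sprintf("[%s,%s)", format(lower, trim = TRUE),
                    ifelse(is.finite(upper), format(upper, trim = TRUE), "Inf"))
  structure(list(edges = edges, labels = labels), class = "depth_binning")
}

#' Assign depths to depth intervals
#'
#' Intervals are half-open `[lower, upper)`: a depth exactly on a boundary
#' falls in the upper (deeper) interval; the deepest interval is open above.
#'
#' @param depth numeric vector of depths in metres, `>= 0`; `NA` passes
#'   through as `NA`.
#' @param binning a [depth_binning()] scheme.
#' @return integer state indices in `1..(length(edges)+1)`.
#' @export
bin_depth <- function(depth, binning = depth_binning()) {
  stopifnot(inherits(binning, "depth_binning"))
  depth <- as.numeric(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("negative depth")
  findInterval(depth, binning$edges) + 1L
}

.habitat_levels <- c("Seeps", "Vents", "Seeps and Vents", "Coastal")

#' Encode habitat labels as character states
#'
#' The four recognized habitat categories, in canonical order, are
#' `"Seeps"`, `"Vents"`, `"Seeps and Vents"`, `"Coastal"`.  Matching is
#' case-insensitive, collapses whitespace, accepts singular forms and an
#' `"&"` conjunction.  Unknown labels raise an error naming the offending
#' label — never a silent coercion.
#'
#' @param label character vector of habitat descriptions; `NA` passes through.
#' @return integer state indices in `1..4` following the canonical order.
#' @export
encode_habitat <- function(label) {
  norm <- tolower(gsub("\\s+", " ", trimws(as.character(label))))
  norm <- gsub(" ?& ?", " and ", norm)
  canon <- c("seeps" = 1L, "seep" = 1L,
             "vents" = 2L, "vent" = 2L,
             "seeps and vents" = 3L, "seep and vent" = 3L,
             "vents and seeps" = 3L,
             "coastal" = 4L)
  out <- unname(canon[norm])
  bad <- !is.na(label) & is.na(out)
  if (any(bad))
    stop("unknown habitat label(s): ",
         paste(unique(label[bad]), collapse = ", "))
  out
}

#' Habitat state alphabet
#' @return the four category labels in canonical order.
#' @export
habitat_levels <- function() .habitat_levels

#' Construct a discrete character matrix
#'
#' A `character_matrix` holds, for an ordered set of taxa, one or more named
#' discrete characters, each with a state alphabet, an ordered/unordered flag
#' and per-taxon state indices (`NA` = missing).
#'
#' @param taxa character vector of unique taxon labels.
#' @param characters named list; each element a list with fields `states`
#'   (integer vector parallel to `taxa`, `NA` allowed), `alphabet`
#'   (character vector of state labels) and `ordered` (logical).
#' @return an object of class `character_matrix`.
#' @export
character_matrix <- function(taxa, characters) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxa: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  stopifnot(is.list(characters), !is.null(names(characters)))
  for (nm in names(characters)) {
    ch <- characters[[nm]]
    stopifnot(length(ch$states) == length(taxa))
    st <- ch$states
    if (any(!is.na(st) & (st < 1L | st > length(ch$alphabet))))
      stop("character '", nm, "': state index outside alphabet")
    characters[[nm]]$states <- as.integer(st)
    characters[[nm]]$ordered <- isTRUE(ch$ordered)
  }
  structure(list(taxa = taxa, characters = characters),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa,",
      length(x$characters), "character(s)\n")
  for (nm in names(x$characters)) {
    ch <- x$characters[[nm]]
    cat(sprintf("  %s: %d states (%s), %d missing\n", nm,
                length(ch$alphabet),
                if (ch$ordered) "ordered" else "unordered",
                sum(is.na(ch$states))))
  }
  invisible(x)
}

#' Extract one character as a named state vector
#'
#' @param cm a [character_matrix()].
#' @param name character name.
#' @param drop_missing drop taxa with missing state (default `TRUE`).
#' @return named integer vector of state indices (names = taxa).
#' @export
character_states <- function(cm, name, drop_missing = TRUE) {
  stopifnot(inherits(cm, "character_matrix"))
  if (!name %in% names(cm$characters))
    stop("no such character: ", name)
  st <- setNames(cm$characters[[name]]$states, cm$taxa)
  if (drop_missing) st <- st[!is.na(st)]
  st
}

#' Read a taxon/depth/habitat table
#'
#' Reads a TSV with header columns `taxon`, `max_depth_m`, `habitat` and
#' builds a [character_matrix()] with an (optionally ordered) depth character
#' discretized through [bin_depth()] and a 4-state habitat character through
#' [encode_habitat()].  Empty cells become missing states.
#'
#' @param path TSV file path.
#' @param binning a [depth_binning()] scheme.
#' @param depth_ordered flag the depth character as ordered (default `FALSE`,
#'   matching unweighted-parsimony treatment; see [step_matrix()]).
#' @return a [character_matrix()] with characters `depth` and `habitat`.
#' @export
read_character_table <- function(path, binning = depth_binning(),
                                 depth_ordered = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "max_depth_m", "habitat")
  if (!all(need %in% names(df)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  depth_raw <- df$max_depth_m
  empty <- is.na(depth_raw) | !nzchar(trimws(as.character(depth_raw)))
  depth_num <- suppressWarnings(as.numeric(as.character(depth_raw)))
  if (any(!empty & is.na(depth_num)))
    stop("unparseable depth for taxon: ",
         paste(df$taxon[!empty & is.na(depth_num)], collapse = ", "))
  depth_states <- ifelse(empty, NA_integer_, bin_depth(depth_num, binning))
  hab_raw <- as.character(df$habitat)
  hab_empty <- is.na(hab_raw) | !nzchar(trimws(hab_raw))
  hab_states <- rep(NA_integer_, nrow(df))
  hab_states[!hab_empty] <- encode_habitat(hab_raw[!hab_empty])
  character_matrix(df$taxon, list(
    depth = list(states = as.integer(depth_states), alphabet = binning$labels,
                 ordered = depth_ordered),
    habitat = list(states = hab_states, alphabet = .habitat_levels,
                   ordered = FALSE)))
}

#' Write a character matrix as TSV
#'
#' One column per character holding state indices (1-based; empty = missing).
#' [read_character_matrix_tsv()] reads it back; the round trip preserves all
#' state assignments.
#'
#' @param cm a [character_matrix()].
#' @param path output file.
#' @export
write_character_matrix_tsv <- function(cm, path) {
  stopifnot(inherits(cm, "character_matrix"))
  df <- data.frame(taxon = cm$taxa, stringsAsFactors = FALSE)
  for (nm in names(cm$characters)) df[[nm]] <- cm$characters[[nm]]$states
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_character_matrix_tsv
#' @param alphabets named list of state alphabets (one per character column);
#'   defaults to `1..max` labels.
#' @param ordered named logical vector of ordered flags.
#' @export
read_character_matrix_tsv <- function(path, alphabets = NULL, ordered = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("taxon" %in% names(df))
  chars <- list()
  for (nm in setdiff(names(df), "taxon")) {
    st <- as.integer(df[[nm]])
    alpha <- if (!is.null(alphabets[[nm]])) alphabets[[nm]]
             else as.character(seq_len(max(st, na.rm = TRUE)))
    chars[[nm]] <- list(states = st, alphabet = alpha,
                        ordered = isTRUE(ordered[nm]))
  }
  character_matrix(df$taxon, chars)
}

# NEXUS interoperability ------------------------------------------------

.nexus_symbols <- c(0:9, LETTERS)

#' Write a character matrix as a NEXUS CHARACTERS block
#'
#' Classic character-tracing programs read discrete matrices from NEXUS DATA
#' blocks; this writes a `#NEXUS` file with TAXA and CHARACTERS blocks, a
#' `SYMBOLS` line covering the largest state alphabet, `MISSING=?` and one
#' character per column.
#'
#' @param cm a [character_matrix()].
#' @param path output file.
#' @export
write_nexus_characters <- function(cm, path) {
  stopifnot(inherits(cm, "character_matrix"))
  kmax <- max(vapply(cm$characters, function(ch) length(ch$alphabet),
                     integer(1)))
  if (kmax > length(.nexus_symbols)) stop("alphabet too large for NEXUS")
  syms <- .nexus_symbols[seq_len(kmax)]
  rows <- vapply(seq_along(cm$taxa), function(i) {
    paste0(vapply(cm$characters, function(ch) {
      s <- ch$states[i]
      if (is.na(s)) "?" else as.character(syms[s])
    }, character(1)), collapse = "")
  }, character(1))
  safe <- gsub("[^A-Za-z0-9_.]", "_", cm$taxa)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", length(cm$taxa)),
    paste0("  TAXLABELS ", paste(safe, collapse = " "), ";"),
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", length(cm$characters)),
    sprintf("  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"%s\";",
            paste(syms, collapse = "")),
    "  MATRIX"), con)
  writeLines(sprintf("    %s %s", format(safe), rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Read a NEXUS CHARACTERS/DATA block
#'
#' Parses the subset of NEXUS written by [write_nexus_characters()] (and by
#' common character-matrix exporters): one symbol column per character,
#' `MISSING=?`.  Alphabets and ordered flags may be supplied; otherwise the
#' alphabet is taken from the SYMBOLS line.
#'
#' @param path NEXUS file.
#' @param names character names to assign to columns (default `char1`, ...).
#' @return a [character_matrix()].
#' @export
read_nexus_characters <- function(path, names = NULL) {
  lines <- readLines(path)
  if (!grepl("^#NEXUS", lines[1], ignore.case = TRUE))
    stop("not a NEXUS file")
  fmt <- grep("FORMAT", lines, ignore.case = TRUE, value = TRUE)
  syms <- .nexus_symbols
  if (length(fmt) && grepl("SYMBOLS", fmt[1], ignore.case = TRUE)) {
    s <- sub('.*SYMBOLS="([^"]*)".*', "\\1", fmt[1])
    syms <- strsplit(gsub(" ", "", s), "")[[1]]
  }
  i0 <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (!length(i0)) stop("no MATRIX found")
  body <- lines[(i0[1] + 1L):length(lines)]
  stop_at <- grep("^\\s*;", body)
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  body <- trimws(body[nzchar(trimws(body))])
  parts <- strsplit(body, "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  rows <- vapply(parts, function(p) p[[length(p)]], character(1))
  nch <- nchar(rows[1])
  if (any(nchar(rows) != nch)) stop("ragged NEXUS matrix")
  if (is.null(names)) names <- paste0("char", seq_len(nch))
  chars <- list()
  for (j in seq_len(nch)) {
    col <- substr(rows, j, j)
    st <- match(col, syms)
    st[col == "?"] <- NA_integer_
    if (any(is.na(st) & col != "?"))
      stop("unknown symbol in NEXUS matrix: ",
           paste(unique(col[is.na(st) & col != "?"]), collapse = ", "))
    kj <- max(st, na.rm = TRUE)
    chars[[names[j]]] <- list(states = st,
                              alphabet = as.character(syms[seq_len(kj)]),
                              ordered = FALSE)
  }
  character_matrix(taxa, chars)
}

#' Reconcile a character matrix with a tree
#'
#' @param cm a [character_matrix()].
#' @param tree a `phylo` object.
#' @return a list with `tree_only` (tips absent from the matrix),
#'   `matrix_only` (taxa absent from the tree) and `shared` (the pruned
#'   intersection used downstream).  Errors when the intersection is empty.
#' @export
validate_against_tree <- function(cm, tree) {
  stopifnot(inherits(cm, "character_matrix"), inherits(tree, "phylo"))
  shared <- intersect(tree$tip.label, cm$taxa)
  if (length(shared) == 0L)
    stop("no taxa shared between tree and character matrix")
  list(tree_only = setdiff(tree$tip.label, cm$taxa),
       matrix_only = setdiff(cm$taxa, tree$tip.label),
       shared = shared)
}
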
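#' Read a Newick tree string or file
#'
#' Parses a rooted Newick tree with branch lengths into an [ape::phylo]
#' object, validates it, and resolves any polytomies into bifurcations with
#' zero-length edges. The resolution is deterministic (input order, via
#' `ape::multi2di(random = FALSE)`); all likelihoods in this package are
#' invariant to the resolution order because the inserted edges have length
#' zero.
#'
#' @param text Newick string (used if `file` is missing).
#' @param file path to a Newick file.
#' @return A rooted, bifurcating `phylo` object with branch lengths.
#' @details Branch lengths are required on every edge (a root edge is
#'   optional and ignored); duplicate tip labels and negative branch lengths
#'   are errors. Zero-length terminal branches are permitted.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    tr <- suppressWarnings(ape::read.tree(file))
  } else {
    if (is.null(text)) stop("supply `text` or `file`")
    tr <- suppressWarnings(ape::read.tree(text = text))
  }
  if (is.null(tr)) stop("malformed Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree")
    tr <- tr[[1L]]
  }
  validate_phylogeny(tr)
}

#' Validate (and canonicalize) a phylogeny
#'
#' Checks the structural invariants every downstream likelihood assumes:
#' branch lengths present and non-negative, unique tip labels, single root,
#' and bifurcating internal nodes (polytomies are resolved deterministically
#' with zero-length edges).
#'
#' @param tree a `phylo` object.
#' @return the validated, bifurcating `phylo` object.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 tips")
  # a basal trichotomy reads as "unrooted" in ape; resolve before the check
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree must be rooted")
  tree
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly if written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `keep`: unsampled tips are dropped and
#' resulting degree-2 nodes are suppressed with their branch lengths summed,
#' so all pairwise path (patristic) distances among retained tips are
#' preserved.
#'
#' @param tree a `phylo` object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("`keep` is empty")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0L)
    stop("species not in tree: ", paste(head(missing, 5L), collapse = ", "))
  if (length(keep) < 2L)
    stop("cannot prune to fewer than 2 tips (no phylogeny)")
  ape::keep.tip(tree, keep)
}

#' Check whether a tree is ultrametric
#'
#' All root-to-tip distances must agree within `rel_tol` of their mean.
#'
#' @param tree a `phylo` object.
#' @param rel_tol relative tolerance (default `1e-6`).
#' @return list with `ok` (logical) and `max_deviation` (max relative
#'   deviation of a root-to-tip distance from the mean).
#' @export
validate_ultrametric <- function(tree, rel_tol = 1e-6) {
  depths <- node_depths(tree)
  tipd <- depths[seq_len(ape::Ntip(tree))]
  m <- mean(tipd)
  dev <- if (m > 0) max(abs(tipd - m)) / m else max(abs(tipd - m))
  list(ok = dev <= rel_tol, max_deviation = dev)
}

# Distance from the root to every node (tips first), edge-sum down-pass.
node_depths <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nmax <- max(tree$edge)
  depth <- numeric(nmax)
  root <- tree$edge[nrow(tree$edge), 1L]
  # preorder: reverse postorder visits parents before children
  for (i in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    depth[ch] <- depth[par] + tree$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Normalize species names
#'
#' Species matching between trees and tables is exact string match after
#' replacing whitespace with underscores and trimming.
#'
#' @param x character vector of names.
#' @return normalized names.
#' @export
normalize_species_names <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ \t]+", "_", x)
}

#' Read a tip-state table
#'
#' Reads a UTF-8 TSV with header columns `species`, `state`, and optionally
#' `alt_state`. States may be coded `0`/`1`, `GSD`/`TSD`, or left blank /
#' `NA` / `unknown` for missing. `alt_state` (the alternative
#' mixed/equivocal assignment) defaults to `state` where absent.
#'
#' @param file path to a TSV file.
#' @return a `data.frame` with columns `species`, `state`, `alt_state`
#'   (integer 0 = GSD, 1 = TSD, `NA` = unknown).
#' @export
read_state_table <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(d)))
    stop("state table needs columns `species` and `state`")
  out <- data.frame(
    species = normalize_species_names(d$species),
    state = .parse_state(d$state),
    stringsAsFactors = FALSE
  )
  out$alt_state <- if ("alt_state" %in% names(d)) .parse_state(d$alt_state)
                   else out$state
  out$alt_state[is.na(out$alt_state)] <- out$state[is.na(out$alt_state)]
  if (anyDuplicated(out$species)) stop("duplicate species in state table")
  out
}

.parse_state <- function(x) {
  x <- trimws(toupper(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0", "GSD")] <- 0L
  out[x %in% c("1", "TSD")] <- 1L
  bad <- !is.na(x) & x != "" & !(x %in% c("0", "1", "GSD", "TSD",
                                          "NA", "UNKNOWN", "?"))
  if (any(bad)) stop("unparseable states: ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Build a tip-state table from a vector
#'
#' @param states named integer/logical vector (names = species, values in
#'   `{0, 1, NA}`).
#' @param alt_states optional named vector of alternative assignments.
#' @return a tip-state `data.frame` as from [read_state_table()].
#' @export
state_table <- function(states, alt_states = NULL) {
  if (is.null(names(states))) stop("`states` must be named by species")
  out <- data.frame(
    species = normalize_species_names(names(states)),
    state = as.integer(states),
    stringsAsFactors = FALSE
  )
  stopifnot(all(is.na(out$state) | out$state %in% 0:1))
  out$alt_state <- out$state
  if (!is.null(alt_states)) {
    i <- match(normalize_species_names(names(alt_states)), out$species)
    out$alt_state[i[!is.na(i)]] <- as.integer(alt_states)[!is.na(i)]
  }
  out
}

#' Read a tip-value table (lifespan or clade richness)
#'
#' TSV with header columns `species` and `value`. Values must be strictly
#' positive; with `integer = TRUE` (richness counts) they must be whole
#' numbers.
#'
#' @param file path to a TSV file.
#' @param integer require integral values (clade richness counts).
#' @return a `data.frame` with columns `species`, `value`.
#' @export
read_value_table <- function(file, integer = FALSE) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("species", "value") %in% names(d)))
    stop("value table needs columns `species` and `value`")
  v <- as.numeric(d$value)
  if (anyNA(v)) stop("non-numeric values in table")
  if (any(v <= 0)) stop("values must be strictly positive")
  if (integer && any(v != round(v))) stop("richness counts must be integers")
  data.frame(species = normalize_species_names(d$species), value = v,
             stringsAsFactors = FALSE)
}

#' Write a tip-state or tip-value table as TSV
#'
#' @param x a `data.frame`.
#' @param file output path.
#' @export
write_table_tsv <- function(x, file) {
  write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Align a state table to a tree: returns integer vector along tip.label
# (NA = unknown). `column` picks the primary or alternative assignment.
align_states <- function(tree, states, column = c("state", "alt_state")) {
  column <- match.arg(column)
  sp <- normalize_species_names(states$species)
  i <- match(normalize_species_names(tree$tip.label), sp)
  out <- rep(NA_integer_, ape::Ntip(tree))
  out[!is.na(i)] <- states[[column]][i[!is.na(i)]]
  out
}

# Prune tree to tips with known state; returns list(tree, tip_states).
prune_to_known <- function(tree, states, column = "state") {
  s <- align_states(tree, states, column)
  keep <- tree$tip.label[!is.na(s)]
  if (length(keep) < 2L) stop("fewer than 2 tips with known state")
  tr <- if (length(keep) == ape::Ntip(tree)) tree else prune_to_taxa(tree, keep)
  list(tree = tr, tip_states = align_states(tr, states, column))
}
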
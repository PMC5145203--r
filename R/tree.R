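#' Supported phylogenetic trees
#'
#' `gh2_tree` wraps an [ape::phylo] topology together with per-internal-node
#' bootstrap supports (fractions in `[0, 1]`, `NA` where unset, always `NA`
#' on the root) and free-form metadata about how the tree was built.
#'
#' @param phylo An `ape::phylo` object.
#' @param supports Numeric vector of length `phylo$Nnode`, or `NULL`.
#' @param meta Named list of provenance fields.
#' @return A `gh2_tree` object.
#' @export
new_gh2_tree <- function(phylo, supports = NULL, meta = list()) {
  stopifnot(inherits(phylo, "phylo"))
  if (anyDuplicated(phylo$tip.label)) {
    abort(paste0("duplicate leaf label(s): ",
                 paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(supports)) supports <- rep(NA_real_, phylo$Nnode)
  stopifnot(length(supports) == phylo$Nnode)
  structure(list(phylo = phylo, supports = as.numeric(supports), meta = meta),
            class = "gh2_tree")
}

#' @export
print.gh2_tree <- function(x, ...) {
  ns <- x$supports[!is.na(x$supports)]
  cat(sprintf("<gh2_tree> %d tips, %d internal nodes", length(x$phylo$tip.label),
              x$phylo$Nnode))
  if (length(ns)) cat(sprintf(", mean support %.2f", mean(ns)))
  cat("\n")
  invisible(x)
}

#' Read a Newick tree
#'
#' Internal node labels, when numeric, are interpreted as bootstrap supports.
#' A degenerate single-leaf file (`"a;"`) yields a one-tip tree.
#'
#' @param path Newick file (one tree).
#' @return A [new_gh2_tree()] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("Newick file not found: ", path))
  txt <- paste(trimws(readLines(path, warn = FALSE)), collapse = "")
  parse_newick(txt)
}

parse_newick <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt)) abort("empty Newick string")
  if (!grepl("\\(", txt)) {
    # single-leaf degenerate tree
    lab <- sub(";$", "", txt)
    lab <- sub(":.*$", "", lab)
    if (!nzchar(lab) || grepl("[(),]", lab)) abort("malformed Newick string")
    phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
                          Nnode = 1L, edge.length = 0),
                     class = "phylo", order = "cladewise")
    return(new_gh2_tree(phy))
  }
  if (lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE))) !=
      lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))) {
    abort("malformed Newick string: unbalanced parentheses")
  }
  phy <- tryCatch(ape::read.tree(text = if (endsWith(txt, ";")) txt
                                 else paste0(txt, ";")),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) abort("malformed Newick string")
  supports <- rep(NA_real_, phy$Nnode)
  if (!is.null(phy$node.label)) {
    supports <- suppressWarnings(as.numeric(phy$node.label))
  }
  new_gh2_tree(phy, supports)
}

#' Write a tree as Newick
#'
#' Supports are written as internal-node labels; `write_newick` followed by
#' [read_newick()] is the identity on topology, branch lengths (to 1e-9) and
#' supports.
#'
#' @param tree A `gh2_tree`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "gh2_tree"))
  phy <- tree$phylo
  if (length(phy$tip.label) == 1) {
    writeLines(paste0(phy$tip.label, ";"), path)
    return(invisible(path))
  }
  phy$node.label <- ifelse(is.na(tree$supports), "",
                           sprintf("%.10g", tree$supports))
  ape::write.tree(phy, file = path, digits = 10)
  invisible(path)
}

# ---- internal tree utilities -------------------------------------------

# Leaf-label sets of every internal node, in node-number order
# (ntip+1 .. ntip+Nnode). Handles multifurcations.
clade_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets[(ntip + 1):(ntip + phy$Nnode)], function(s) sort(unique(s)))
}

# Canonical bipartition key for an internal node's clade on an unrooted
# tree: take the side not containing the alphabetically first tip, sort,
# and paste. Trivial bipartitions (size < 2 on either side) are dropped by
# callers.
bipartition_keys <- function(phy) {
  tips <- sort(phy$tip.label)
  anchor <- tips[1]
  sets <- clade_sets(phy)
  vapply(sets, function(s) {
    side <- if (anchor %in% s) setdiff(tips, s) else s
    paste(sort(side), collapse = "|")
  }, "")
}
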
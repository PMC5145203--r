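#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times, rebuilds a tree per replicate, and sets
#' the support of each internal edge of the full tree to the fraction of
#' replicates containing the same bipartition. Replicates whose distance
#' matrix contains saturated (undefined) entries are dropped and counted in
#' the metadata. Identical seeds give identical supports.
#'
#' @param msa A `gh2_msa`.
#' @param n_replicates Number of bootstrap replicates (paper protocol: 100).
#' @param seed Integer seed (mandatory: resampling is the only stochastic
#'   step of the tree stage).
#' @param method Distance correction, see [correct_distance()].
#' @param deletion Site-deletion policy, see [p_distance()].
#' @return A `gh2_tree` with supports in `[0, 1]` on internal edges
#'   (`NA` on the root) and metadata (`n_replicates`, `n_dropped`, `seed`,
#'   `method`).
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed,
                              method = c("kimura", "poisson", "none"),
                              deletion = c("pairwise", "complete")) {
  method <- match.arg(method)
  deletion <- match.arg(deletion)
  stopifnot(n_replicates >= 1)
  if (missing(seed)) abort("bootstrap_support() requires an explicit seed")
  full <- nj_tree(distance_from_matrix(msa_matrix(msa), msa$id, method,
                                       deletion))
  keys_full <- bipartition_keys(full$phylo)
  ntip <- length(full$phylo$tip.label)
  counts <- setNames(rep(0L, length(keys_full)), NULL)
  n_dropped <- 0L
  im <- msa_matrix(msa)
  L <- ncol(im)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  cols <- matrix(sample.int(L, L * n_replicates, replace = TRUE),
                 nrow = n_replicates)
  for (r in seq_len(n_replicates)) {
    dr <- tryCatch(
      distance_from_matrix(im[, cols[r, ], drop = FALSE], msa$id, method,
                           deletion),
      error = function(e) NULL)
    if (is.null(dr) || anyNA(dr$d)) {
      n_dropped <- n_dropped + 1L
      next
    }
    tr <- nj_tree(dr)
    hit <- keys_full %in% bipartition_keys(tr$phylo)
    counts <- counts + as.integer(hit)
  }
  eff <- n_replicates - n_dropped
  if (eff < 1) abort("all bootstrap replicates failed (saturated distances)")
  supports <- counts / eff
  # root of the basal trifurcation carries no edge: support NA
  supports[1] <- NA_real_
  full$supports <- supports
  full$meta <- c(full$meta,
                 list(n_replicates = n_replicates, n_dropped = n_dropped,
                      seed = seed, distance = method, deletion = deletion))
  full
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# distance matrix straight from an integer alignment matrix (no gh2_msa
# rebuild per bootstrap replicate)
distance_from_matrix <- function(im, ids, method, deletion) {
  if (deletion == "complete") {
    keep <- colSums(im == 0L) == 0
    if (!any(keep)) abort("no comparable columns under complete deletion")
    im <- im[, keep, drop = FALSE]
  }
  cnt <- .pdist_counts_cpp(im)
  p <- ifelse(cnt$ncomp > 0, cnt$ndiff / pmax(cnt$ncomp, 1L), NA_real_)
  diag(p) <- 0
  d <- correct_distance(p, method)
  attr(d, "saturated") <- NULL
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, p = p), class = "gh2_dist")
}

#' Condense a tree at a support threshold
#'
#' Contracts every internal edge whose support is strictly below
#' `threshold` into a polytomy (edges at exactly the threshold are kept:
#' "condensed at < 50%" reads strictly). The children of a collapsed node
#' keep their own branch lengths. Condensation is idempotent and never
#' increases the number of internal edges.
#'
#' @param tree A `gh2_tree` with supports.
#' @param threshold Support threshold in `[0, 1]` (default 0.5).
#' @return A condensed `gh2_tree`; `meta$n_collapsed` counts removed edges.
#' @export
condense_tree <- function(tree, threshold = 0.5) {
  stopifnot(inherits(tree, "gh2_tree"))
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  node_support <- function(node) tree$supports[node - ntip]
  edge_len <- function(parent, child) {
    k <- which(phy$edge[, 1] == parent & phy$edge[, 2] == child)
    if (!is.null(phy$edge.length)) phy$edge.length[k] else NA_real_
  }
  n_collapsed <- 0L
  build <- function(node) {
    # returns list of newick fragments (children already spliced)
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    frags <- character(0)
    for (ch in kids) {
      len <- edge_len(node, ch)
      lenstr <- if (is.na(len)) "" else sprintf(":%.10g", len)
      if (ch <= ntip) {
        frags <- c(frags, paste0(phy$tip.label[ch], lenstr))
      } else {
        sup <- node_support(ch)
        sub <- build(ch)
        if (!is.na(sup) && sup < threshold) {
          # contract this edge: splice grandchildren into the current node
          n_collapsed <<- n_collapsed + 1L
          frags <- c(frags, sub)
        } else {
          supstr <- if (is.na(sup)) "" else sprintf("%.10g", sup)
          frags <- c(frags, paste0("(", paste(sub, collapse = ","), ")",
                                   supstr, lenstr))
        }
      }
    }
    frags
  }
  nwk <- paste0("(", paste(build(root), collapse = ","), ");")
  out <- parse_newick(nwk)
  keep_meta <- tree$meta[setdiff(names(tree$meta),
                                 c("condense_threshold", "n_collapsed"))]
  out$meta <- c(keep_meta, list(condense_threshold = threshold,
                                n_collapsed = n_collapsed))
  out
}
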
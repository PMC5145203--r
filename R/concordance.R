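#' Concordance between leaf labels and tree clades
#'
#' For each label value (e.g. a DA type): is the label monophyletic, what is
#' the smallest clade containing all its leaves, and how pure is that clade
#' (label members / clade members)? Monophyly is tested on the unrooted
#' topology (a label is monophyletic when some bipartition separates exactly
#' its leaves; single leaves are monophyletic by convention). Additionally a
#' nesting matrix reports, per ordered label pair (A, B), whether all of A's
#' leaves lie strictly inside B's smallest containing clade — the relation
#' behind statements like "bicistronic enzymes emerge from branches of the
#' canonical clade".
#'
#' @param tree A `gh2_tree`.
#' @param labels Named character vector (names = leaf labels of the tree) or
#'   tibble with columns `seq_id`, `label`. Every leaf must be labeled.
#' @return A `gh2_concordance` object: list with `per_label` tibble
#'   (`label`, `n`, `monophyletic`, `clade_size`, `purity`) and `nesting`
#'   tibble (`inner`, `outer`, `nested`).
#' @export
concordance <- function(tree, labels) {
  stopifnot(inherits(tree, "gh2_tree"))
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, labels$seq_id)
  }
  tips <- tree$phylo$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing)) {
    abort(paste0("unlabeled leaf(s): ", paste(missing, collapse = ", ")))
  }
  lab <- labels[tips]
  all_tips <- sort(tips)
  # candidate clades on the unrooted topology: rooted clades plus their
  # complements (both sides of every split)
  rooted <- clade_sets(tree$phylo)
  sets <- unique(c(rooted, lapply(rooted, function(s)
    sort(setdiff(all_tips, s))), list(all_tips)))
  sets <- sets[lengths(sets) > 0]
  smallest_of <- function(lv) {
    members <- tips[lab == lv]
    containing <- sets[vapply(sets, function(s) all(members %in% s), TRUE)]
    containing[[which.min(lengths(containing))]]
  }
  per <- unique(lab) |> sort() |> purrr::map(function(lv) {
    members <- sort(tips[lab == lv])
    mono <- length(members) == 1 ||
      any(vapply(sets, function(s) identical(s, members), TRUE))
    smallest <- smallest_of(lv)
    tibble(label = lv, n = length(members), monophyletic = mono,
           clade_size = length(smallest),
           purity = length(members) / length(smallest))
  }) |> bind_rows()
  lv <- per$label
  nesting <- tidyr::expand_grid(inner = lv, outer = lv) |>
    filter(.data$inner != .data$outer) |>
    dplyr::rowwise() |>
    mutate(nested = {
      inner_members <- tips[lab == .data$inner]
      outer_clade <- smallest_of(.data$outer)
      all(inner_members %in% outer_clade) &&
        length(outer_clade) > length(inner_members)
    }) |>
    ungroup()
  structure(list(per_label = per, nesting = nesting),
            class = "gh2_concordance")
}

#' @export
print.gh2_concordance <- function(x, ...) {
  cat("<gh2_concordance>\n")
  print(x$per_label)
  invisible(x)
}

#' Subcluster a distance matrix and select representatives
#'
#' Reproduces the representative-selection protocol: sequences are first
#' subclustered (average-linkage height cut of the distance matrix), then a
#' quota of representatives is drawn with at least one member per
#' subcluster, the remainder filled by seeded uniform sampling. A quota
#' larger than the pool returns the whole pool (logged in the attributes).
#' Identical seeds give identical selections.
#'
#' @param d A `gh2_dist` (or symmetric matrix with dimnames).
#' @param h Height (distance) at which to cut the average-linkage tree.
#' @param quota Total number of representatives to select.
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `seq_id`, `subcluster`, `selected`; attribute
#'   `"quota_truncated"` is `TRUE` when the quota exceeded the pool.
#' @export
subcluster_and_select <- function(d, h, quota, seed) {
  if (missing(seed)) abort("subcluster_and_select() requires an explicit seed")
  D <- if (inherits(d, "gh2_dist")) (d$d %||% d$p) else d
  ids <- if (inherits(d, "gh2_dist")) d$ids else rownames(d)
  hc <- hclust(as.dist(D), method = "average")
  sub <- cutree(hc, h = h)
  out <- tibble(seq_id = ids, subcluster = unname(sub[ids]))
  truncated <- quota >= length(ids)
  if (truncated) {
    out$selected <- TRUE
    attr(out, "quota_truncated") <- TRUE
    return(out)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  picked <- character(0)
  for (cl in sort(unique(out$subcluster))) {
    pool <- sort(out$seq_id[out$subcluster == cl])
    picked <- c(picked, pool[sample.int(length(pool), 1)])
  }
  remaining <- sort(setdiff(out$seq_id, picked))
  extra <- max(0, quota - length(picked))
  if (extra > 0 && length(remaining)) {
    picked <- c(picked, remaining[sample.int(length(remaining),
                                             min(extra, length(remaining)))])
  }
  out$selected <- out$seq_id %in% picked
  attr(out, "quota_truncated") <- FALSE
  out
}
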
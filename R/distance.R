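#' Pairwise p-distances from an alignment
#'
#' Fraction of differing residues among comparable columns per sequence
#' pair. Under `pairwise` deletion a column is comparable for a pair iff
#' both rows hold a residue; under `complete` deletion every column with a
#' gap in any row is removed first. Pairs with zero comparable columns get
#' `NA` and are flagged.
#'
#' @param msa A `gh2_msa`.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return A `gh2_dist` object: list with `ids`, `p` (symmetric matrix,
#'   zero diagonal), `ncomp` (comparable-column counts), and
#'   `incomparable` (logical matrix flag).
#' @export
p_distance <- function(msa, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  im <- msa_matrix(msa)
  if (deletion == "complete") {
    keep <- colSums(im == 0L) == 0
    if (!any(keep)) abort("no comparable columns under complete deletion")
    im <- im[, keep, drop = FALSE]
  }
  cnt <- .pdist_counts_cpp(im)
  p <- ifelse(cnt$ncomp > 0, cnt$ndiff / pmax(cnt$ncomp, 1L), NA_real_)
  diag(p) <- 0
  incomparable <- cnt$ncomp == 0
  diag(incomparable) <- FALSE
  if (any(incomparable)) {
    warn(sprintf("%d sequence pair(s) share no comparable columns",
                 sum(incomparable) / 2))
  }
  dimnames(p) <- list(msa$id, msa$id)
  structure(list(ids = msa$id, p = p, ncomp = cnt$ncomp,
                 incomparable = incomparable),
            class = "gh2_dist")
}

#' Correct observed distances for multiple substitutions
#'
#' `none` returns p unchanged; `poisson` applies `-log(1 - p)`; `kimura`
#' applies the protein correction `-log(1 - p - 0.2 p^2)`. Values of p at or
#' beyond the method's domain bound are flagged saturated (`NA` with a
#' `saturated` attribute).
#'
#' @param p Numeric vector or matrix of observed proportions in `[0, 1)`.
#' @param method `"kimura"`, `"poisson"` or `"none"`.
#' @return Corrected distances, same shape as `p`, with attribute
#'   `saturated` (logical, same shape).
#' @export
correct_distance <- function(p, method = c("kimura", "poisson", "none")) {
  method <- match.arg(method)
  arg <- switch(method, none = NULL, poisson = 1 - p,
                kimura = 1 - p - 0.2 * p^2)
  if (method == "none") {
    sat <- is.na(p) | p < 0 | p > 1
    out <- p
  } else {
    sat <- is.na(arg) | arg <= 0
    out <- ifelse(sat, NA_real_, -log(pmax(arg, 1e-300)))
  }
  attr(out, "saturated") <- sat
  out
}

#' Evolutionary distance matrix from an alignment
#'
#' [p_distance()] followed by [correct_distance()], returning a `gh2_dist`
#' ready for [nj_tree()].
#'
#' @inheritParams p_distance
#' @param method Correction method, see [correct_distance()].
#' @return A `gh2_dist` with elements `ids`, `d` (corrected), `p`,
#'   `saturated`.
#' @export
distance_matrix <- function(msa, method = c("kimura", "poisson", "none"),
                            deletion = c("pairwise", "complete")) {
  method <- match.arg(method)
  pd <- p_distance(msa, deletion)
  d <- correct_distance(pd$p, method)
  sat <- attr(d, "saturated")
  attr(d, "saturated") <- NULL
  dimnames(d) <- dimnames(pd$p)
  structure(list(ids = pd$ids, d = d, p = pd$p,
                 saturated = sat | pd$incomparable),
            class = "gh2_dist")
}
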
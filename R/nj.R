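#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Ties in Q are
#' broken by the lowest index pair (row-major scan, strict improvement
#' only), so the result is deterministic for a given matrix. Negative branch
#' lengths are clamped to zero and the total clamped deficit is recorded in
#' the tree metadata. The returned tree is unrooted (represented with a
#' basal trifurcation); supports are unset.
#'
#' @param d A `gh2_dist`, or a symmetric numeric matrix with id dimnames.
#' @return A [new_gh2_tree()] with `meta$n_clamped` and
#'   `meta$clamped_deficit`.
#' @export
nj_tree <- function(d) {
  D <- if (inherits(d, "gh2_dist")) (d$d %||% d$p) else d
  ids <- if (inherits(d, "gh2_dist")) d$ids else rownames(d)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), length(ids) == nrow(D))
  if (anyNA(D)) abort("distance matrix contains NA (saturated pairs?)")
  if (max(abs(D - t(D))) > 1e-9 || any(diag(D) != 0) || any(D < 0)) {
    abort("distance matrix must be symmetric, non-negative, zero diagonal")
  }
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  fmt <- function(x) sprintf("%.10g", x)
  labs <- ids                  # newick fragment per active node
  n_clamped <- 0L
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) {
      n_clamped <<- n_clamped + 1L
      deficit <<- deficit + x
      0
    } else x
  }
  while (n > 3) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, `+`)
    best <- c(1L, 2L); bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))))
    newlab <- paste0("(", labs[i], ":", fmt(li), ",", labs[j], ":", fmt(lj), ")")
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    labs <- c(labs[keep], newlab)
    n <- n - 1L
  }
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", labs[1], ":", fmt(la), ",", labs[2], ":", fmt(lb), ",",
                labs[3], ":", fmt(lc), ");")
  phy <- ape::read.tree(text = nwk)
  new_gh2_tree(phy, meta = list(method = "nj", n_clamped = n_clamped,
                                clamped_deficit = deficit))
}
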
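#' Protein scoring scheme
#'
#' Substitution matrix plus affine gap penalties for global alignment. The
#' default is BLOSUM62 (taken from Biostrings, restricted to the 20 amino
#' acids plus X) with gap open -11 and gap extend -1, the community default
#' for global protein alignment. A gap of length k costs
#' `open + (k - 1) * extend`.
#'
#' @param matrix Square numeric substitution matrix with residue dimnames,
#'   or `"BLOSUM62"`.
#' @param gap_open,gap_extend Negative penalties with
#'   `gap_open <= gap_extend < 0`.
#' @return A `gh2_scoring` list: `S`, `open`, `extend`, `alphabet`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -11,
                           gap_extend = -1) {
  if (identical(matrix, "BLOSUM62")) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    ab <- gh2_alphabet()
    matrix <- data_env$BLOSUM62[ab, ab]
  }
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            isTRUE(all.equal(matrix, t(matrix))),
            gap_open <= gap_extend, gap_extend < 0)
  structure(list(S = matrix, open = gap_open, extend = gap_extend,
                 alphabet = rownames(matrix)),
            class = "gh2_scoring")
}

seq_to_idx <- function(x, alphabet) {
  idx <- match(chars(x), alphabet)
  if (anyNA(idx)) {
    abort(paste0("residue(s) outside the scoring alphabet: ",
                 paste(unique(chars(x)[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh alignment maximising the affine-gap score, with
#' deterministic tie-breaking during traceback (match/mismatch preferred
#' over a gap in `a`, preferred over a gap in `b`).
#'
#' @param a,b Non-empty residue strings.
#' @param scheme A [scoring_scheme()].
#' @return A `gh2_alignment` list: `aligned_a`, `aligned_b` (equal-length
#'   strings over residues and `-`), `score`.
#' @export
nw_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) abort("nw_align() requires non-empty sequences")
  res <- .nw_align_cpp(seq_to_idx(a, scheme$alphabet),
                       seq_to_idx(b, scheme$alphabet),
                       scheme$S, scheme$open, scheme$extend)
  ca <- chars(a); cb <- chars(b)
  ops <- res$ops
  out_a <- character(length(ops)); out_b <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != 2L) { i <- i + 1L; out_a[k] <- ca[i] } else out_a[k] <- "-"
    if (ops[k] != 1L) { j <- j + 1L; out_b[k] <- cb[j] } else out_b[k] <- "-"
  }
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = res$score),
            class = "gh2_alignment")
}

#' Percent identity of a pairwise alignment
#'
#' Matches divided by a chosen denominator. Columns with a gap in either row
#' never count as matches; gap-gap columns are never counted at all.
#' Denominators: `aligned_columns` (columns with residues in both rows),
#' `shorter_seq` (length of the shorter input), `reference_positions`
#' (residues of the *second* sequence sitting in residue-residue columns;
#' the pairing used when comparing a query region against a reference
#' module).
#'
#' @param alignment A `gh2_alignment` (or list with `aligned_a`,
#'   `aligned_b`).
#' @param denominator One of `"aligned_columns"`, `"shorter_seq"`,
#'   `"reference_positions"`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(alignment,
                             denominator = c("aligned_columns", "shorter_seq",
                                             "reference_positions")) {
  denominator <- match.arg(denominator)
  ca <- chars(alignment$aligned_a)
  cb <- chars(alignment$aligned_b)
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb)
  den <- switch(denominator,
    aligned_columns = sum(both),
    shorter_seq = min(sum(ca != "-"), sum(cb != "-")),
    reference_positions = sum(both))
  if (den == 0) return(0)
  matches / den
}

# number of reference (second-row) residues aligned to query residues, and
# reference length — the coverage ingredients for module tagging
alignment_ref_coverage <- function(alignment) {
  ca <- chars(alignment$aligned_a)
  cb <- chars(alignment$aligned_b)
  list(aligned_ref = sum(ca != "-" & cb != "-"), ref_len = sum(cb != "-"))
}

# L x K residue-frequency profile of aligned rows (gap mass dropped)
msa_profile <- function(rows, alphabet) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  prof <- matrix(0, L, length(alphabet))
  for (k in seq_along(alphabet)) {
    prof[, k] <- colSums(mat == alphabet[k]) / nrow(mat)
  }
  prof
}

apply_ops_rows <- function(rows, ops, consume_code) {
  # insert gaps into aligned rows wherever this side is not consumed
  n <- length(ops)
  take <- ops != consume_code  # columns where this side advances
  out <- matrix("-", length(rows), n)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  out[, take] <- mat
  apply(out, 1, paste, collapse = "")
}

#' Progressive multiple sequence alignment
#'
#' Guide-tree progressive alignment: pairwise k-mer-count distances feed a
#' UPGMA guide tree (average-linkage [stats::hclust()]), and profiles are
#' merged leaf-to-root with affine profile-profile alignment using the same
#' scoring scheme as [nw_align()]. For two sequences the result equals the
#' pairwise [nw_align()] alignment. Degapping any output row reproduces the
#' corresponding input sequence exactly (asserted).
#'
#' @param seqs Tibble with `id`, `residues` (at least 2 rows), or a named
#'   character vector.
#' @param scheme A [scoring_scheme()].
#' @param k K-mer size for guide-tree distances (reduced automatically for
#'   very short sequences).
#' @return A `gh2_msa` object: tibble with columns `id`, `aligned`, plus
#'   attribute `n_columns`.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3) {
  if (is.character(seqs)) seqs <- tibble(id = names(seqs), residues = unname(seqs))
  stopifnot(nrow(seqs) >= 2, !anyDuplicated(seqs$id))
  n <- nrow(seqs)
  k <- max(1, min(k, min(nchar(seqs$residues))))
  kmer_sets <- lapply(seqs$residues, function(s) {
    L <- nchar(s) - k + 1
    table(substring(s, 1:L, 1:L + k - 1))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- kmer_sets[[i]]; b <- kmer_sets[[j]]
      common <- intersect(names(a), names(b))
      shared <- sum(pmin(a[common], b[common]))
      D[i, j] <- D[j, i] <- 1 - shared / min(sum(a), sum(b))
    }
  }
  groups <- as.list(seq_len(n))
  rows <- as.list(seqs$residues)
  if (n == 2) {
    merged_ids <- c(1L, 2L)
    al <- nw_align(seqs$residues[1], seqs$residues[2], scheme)
    aligned <- c(al$aligned_a, al$aligned_b)
  } else {
    hc <- hclust(as.dist(D), method = "average")
    node_rows <- vector("list", n - 1)
    node_ids <- vector("list", n - 1)
    get <- function(x) {
      if (x < 0) list(rows = rows[[-x]], ids = -x)
      else list(rows = node_rows[[x]], ids = node_ids[[x]])
    }
    for (m in seq_len(n - 1)) {
      a <- get(hc$merge[m, 1]); b <- get(hc$merge[m, 2])
      if (length(a$ids) == 1 && length(b$ids) == 1) {
        al <- nw_align(a$rows, b$rows, scheme)
        node_rows[[m]] <- c(al$aligned_a, al$aligned_b)
      } else {
        pa <- msa_profile(a$rows, scheme$alphabet)
        pb <- msa_profile(b$rows, scheme$alphabet)
        res <- .profile_align_cpp(pa, pb, scheme$S, scheme$open, scheme$extend)
        node_rows[[m]] <- c(apply_ops_rows(a$rows, res$ops, 2L),
                            apply_ops_rows(b$rows, res$ops, 1L))
      }
      node_ids[[m]] <- c(a$ids, b$ids)
    }
    merged_ids <- node_ids[[n - 1]]
    aligned <- node_rows[[n - 1]]
  }
  out <- tibble(id = seqs$id[merged_ids], aligned = aligned) |>
    dplyr::slice(match(seqs$id, .data$id))
  # invariant: degapping recovers the inputs
  stopifnot(identical(gsub("-", "", out$aligned, fixed = TRUE),
                      seqs$residues))
  new_gh2_msa(out)
}

new_gh2_msa <- function(tbl) {
  stopifnot(all(c("id", "aligned") %in% names(tbl)),
            length(unique(nchar(tbl$aligned))) == 1)
  structure(tbl, class = c("gh2_msa", class(tibble())),
            n_columns = nchar(tbl$aligned[1]))
}

#' Build an MSA object from pre-aligned rows
#'
#' Accepts externally computed alignments (e.g. aligned FASTA from another
#' aligner) so the downstream tree and conservation stages can run on exact
#' third-party output.
#'
#' @param x Tibble with `id`, `aligned`, or a named character vector of
#'   equal-length gapped strings.
#' @return A `gh2_msa`.
#' @export
as_msa <- function(x) {
  if (is.character(x)) x <- tibble(id = names(x), aligned = unname(x))
  new_gh2_msa(as_tibble(x[, c("id", "aligned")]))
}

#' Read / write aligned FASTA and relaxed PHYLIP
#'
#' @param path File path.
#' @return `read_alignment()` returns a `gh2_msa`; writers return `path`.
#' @export
read_alignment <- function(path) {
  x <- read_fasta_gapped(path)
  new_gh2_msa(tibble(id = x$id, aligned = x$residues))
}

# FASTA reader tolerating gap characters (alignment interchange)
read_fasta_gapped <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) abort(paste0("empty FASTA: ", path))
  tibble(id = sub("\\s.*$", "", names(set)),
         residues = unname(toupper(as.character(set))))
}

#' @rdname read_alignment
#' @param msa A `gh2_msa`.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(tibble(id = msa$id, residues = msa$aligned), path)
}

#' @rdname read_alignment
#' @export
write_phylip <- function(msa, path) {
  lines <- c(sprintf(" %d %d", nrow(msa), attr(msa, "n_columns")),
             sprintf("%s  %s", msa$id, msa$aligned))
  writeLines(lines, path)
  invisible(path)
}

# integer matrix view of an MSA: rows = sequences, 0 = gap
msa_matrix <- function(msa, alphabet = gh2_alphabet()) {
  mat <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  im <- matrix(match(mat, alphabet, nomatch = 0L), nrow(mat), ncol(mat))
  rownames(im) <- msa$id
  im
}
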
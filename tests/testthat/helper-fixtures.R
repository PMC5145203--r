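# Small in-code fixtures and independent oracles shared across tests.

mk_seqs <- function(...) {
  x <- c(...)
  tibble::tibble(id = names(x), residues = unname(x), description = "")
}

mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    seq_id = vapply(rows, `[[`, "", 1),
    domain = vapply(rows, `[[`, "", 2),
    env_start = as.integer(vapply(rows, function(r) as.numeric(r[[3]]), 1)),
    env_end = as.integer(vapply(rows, function(r) as.numeric(r[[4]]), 1)),
    model_coverage = vapply(rows, function(r) as.numeric(r[[5]]), 1),
    source = "test"
  )
}

random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# random architecture set over a domain pool, as the long tibble the
# encoders consume
random_architectures <- function(n_seqs, domains = LETTERS[1:5],
                                 max_rep = 3) {
  rows <- list()
  for (i in seq_len(n_seqs)) {
    k <- sample(1:4, 1)
    els <- unlist(lapply(sample(domains, k), function(d) {
      rep(d, sample(1:max_rep, 1))
    }))
    L <- length(els) * 100L
    starts <- seq(1L, by = 100L, length.out = length(els))
    rows[[i]] <- tibble::tibble(seq_id = sprintf("s%04d", i), element = els,
                                start = starts, end = starts + 79L,
                                seq_length = L)
  }
  dplyr::bind_rows(rows)
}

# Exhaustive affine-gap alignment oracle: enumerates every global alignment
# (as op strings over M/X/Y) and scores it with the run-aware affine rule.
# Independent of the DP implementation; only feasible for tiny sequences.
enumerate_align_score <- function(a, b, scheme) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  S <- scheme$S
  open <- scheme$open; ext <- scheme$extend
  best <- -Inf
  rec <- function(i, j, prev_op, acc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, "M", acc + S[ca[i], cb[j]])
    }
    if (i <= length(ca)) {
      rec(i + 1, j, "X", acc + if (prev_op == "X") ext else open)
    }
    if (j <= length(cb)) {
      rec(i, j + 1, "Y", acc + if (prev_op == "Y") ext else open)
    }
  }
  rec(1, 1, "start", 0)
  best
}

# connected components of the thresholded identity graph, by brute force
brute_components <- function(idm, threshold) {
  n <- nrow(idm)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && idm[i, j] >= threshold && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# additive distance matrix from a random tree, with optional multiplicative
# noise
random_additive_matrix <- function(n, noise = 0) {
  phy <- ape::rtree(n, br = function(m) runif(m, 0.15, 1))
  D <- ape::cophenetic.phylo(phy)
  ids <- sort(rownames(D))
  D <- D[ids, ids]
  if (noise > 0) {
    f <- matrix(runif(n * n, 1 - noise, 1 + noise), n, n)
    f[lower.tri(f)] <- t(f)[lower.tri(f)]
    D <- D * f
    diag(D) <- 0
  }
  list(D = D, phy = phy)
}

mutate_cols <- function(s, pos) {
  cc <- strsplit(s, "")[[1]]
  for (i in pos) cc[i] <- setdiff(c("W", "Y"), cc[i])[1]
  paste(cc, collapse = "")
}

# alignment of two clearly separated clades: n_diff invariant-within-clade
# differing columns plus one private substitution per tip
two_clade_msa <- function(n_per_clade = 4, n_cols = 200, n_diff = 60,
                          seed = 1) {
  set.seed(seed)
  base <- random_protein(n_cols)
  other <- mutate_cols(base, seq_len(n_diff))
  rows <- c(setNames(rep(base, n_per_clade),
                     sprintf("a%d", seq_len(n_per_clade))),
            setNames(rep(other, n_per_clade),
                     sprintf("b%d", seq_len(n_per_clade))))
  for (i in seq_along(rows)) {
    rows[i] <- mutate_cols(rows[i], n_diff + i)
  }
  as_msa(rows)
}

unrooted_topology_equal <- function(phy1, phy2) {
  isTRUE(all.equal(phangorn::RF.dist(ape::unroot(phy1), ape::unroot(phy2)), 0))
}
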
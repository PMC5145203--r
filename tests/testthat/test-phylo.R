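test_that("p-distances count differing comparable columns under both deletion modes", {
  msa <- as_msa(c(r1 = "AAAA", r2 = "AAGG", r3 = "AAAA"))
  pd <- p_distance(msa)
  expect_equal(pd$p["r1", "r2"], 0.5)
  expect_equal(pd$p["r1", "r3"], 0)

  msa2 <- as_msa(c(a = "A-AA", b = "AGAA"))
  expect_equal(p_distance(msa2, "pairwise")$p["a", "b"], 0)
  # complete deletion drops the gapped column too
  expect_equal(p_distance(msa2, "complete")$p["a", "b"], 0)

  msa3 <- as_msa(c(a = "A--A", b = "-GG-"))
  expect_warning(pd3 <- p_distance(msa3, "pairwise"), "no comparable")
  expect_true(is.na(pd3$p["a", "b"]))
})

test_that("distance corrections match their closed forms and flag saturation", {
  expect_equal(correct_distance(0, "kimura"), 0, ignore_attr = TRUE)
  expect_equal(correct_distance(0, "poisson"), 0, ignore_attr = TRUE)
  expect_equal(correct_distance(0.3, "none"), 0.3, ignore_attr = TRUE)
  expect_equal(correct_distance(0.1, "kimura"), -log(1 - 0.1 - 0.2 * 0.01),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(correct_distance(0.1, "kimura"), 0.1075852, tolerance = 1e-6,
               ignore_attr = TRUE)
  k95 <- correct_distance(0.95, "kimura")
  expect_true(is.na(k95))
  expect_true(attr(k95, "saturated"))
  p1 <- correct_distance(1, "poisson")
  expect_true(is.na(p1))
})

test_that("neighbor joining recovers a 4-taxon additive tree exactly", {
  # distances generated by hand from (a:1,b:2,(c:3,d:4):5)
  D <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  pm <- ape::cophenetic.phylo(tr$phylo)[letters[1:4], letters[1:4]]
  expect_equal(pm, D, tolerance = 1e-9)
  # ab|cd bipartition present
  truth <- ape::read.tree(text = "((a:1,b:2),(c:3,d:4));")
  expect_true(unrooted_topology_equal(tr$phylo, truth))
})

test_that("three taxa resolve by the closed three-point formulas", {
  D <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  el <- setNames(tr$phylo$edge.length,
                 tr$phylo$tip.label[tr$phylo$edge[, 2]])
  expect_equal(el[["a"]], (5 + 9 - 8) / 2)
  expect_equal(el[["b"]], (5 + 8 - 9) / 2)
  expect_equal(el[["c"]], (9 + 8 - 5) / 2)
})

test_that("neighbor joining is exact on random additive matrices and matches ape", {
  set.seed(701)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    ad <- random_additive_matrix(n)
    tr <- nj_tree(ad$D)
    pm <- ape::cophenetic.phylo(tr$phylo)[rownames(ad$D), rownames(ad$D)]
    expect_equal(pm, ad$D, tolerance = 1e-8)
    expect_true(unrooted_topology_equal(tr$phylo, ad$phy))
    # independent implementation agrees on the topology
    expect_true(unrooted_topology_equal(tr$phylo, ape::nj(ad$D)))
  }
})

test_that("negative branch lengths are clamped and logged", {
  D <- matrix(c(0, 2, 2, 2.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                2.1, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$phylo$edge.length >= 0))
})

test_that("bootstrap supports are deterministic per seed and unanimous on clear splits", {
  msa <- two_clade_msa()
  t1 <- bootstrap_support(msa, n_replicates = 100, seed = 9)
  t2 <- bootstrap_support(msa, n_replicates = 100, seed = 9)
  expect_equal(t1$supports, t2$supports)
  expect_equal(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))

  # the clade split is supported by 60 invariant-difference columns:
  # every replicate contains it
  sets <- gh2arch:::clade_sets(t1$phylo)
  akey <- sprintf("a%d", 1:4)
  idx <- which(vapply(sets, function(s) identical(sort(s), sort(akey)), TRUE) |
                 vapply(sets, function(s)
                   identical(sort(setdiff(t1$phylo$tip.label, s)),
                             sort(akey)), TRUE))
  expect_true(any(t1$supports[idx] == 1.0))

  t3 <- bootstrap_support(msa, n_replicates = 1, seed = 5)
  expect_true(all(t3$supports[-1] %in% c(0, 1)))
  expect_error(bootstrap_support(msa, n_replicates = 10), "seed")
})

test_that("bipartition supports are invariant to row order of the alignment", {
  msa <- two_clade_msa(seed = 3)
  t1 <- bootstrap_support(msa, n_replicates = 50, seed = 11)
  perm <- sample(nrow(msa))
  msa2 <- as_msa(tibble::tibble(id = msa$id[perm],
                                aligned = msa$aligned[perm]))
  t2 <- bootstrap_support(msa2, n_replicates = 50, seed = 11)
  k1 <- gh2arch:::bipartition_keys(t1$phylo)[-1]
  k2 <- gh2arch:::bipartition_keys(t2$phylo)[-1]
  s1 <- setNames(t1$supports[-1], k1)
  s2 <- setNames(t2$supports[-1], k2)
  common <- intersect(k1, k2)
  expect_gt(length(common), 0)
  expect_equal(s1[common], s2[common])
})

test_that("condensation collapses strictly-below-threshold edges and is idempotent", {
  t1 <- gh2arch:::parse_newick("(((a:1,b:1)0.49:1,c:1)0.62:1,d:1,e:1);")
  c1 <- condense_tree(t1, 0.5)
  expect_equal(c1$meta$n_collapsed, 1)
  expect_lt(nrow(c1$phylo$edge), nrow(t1$phylo$edge))

  # support exactly at the threshold is retained
  t2 <- gh2arch:::parse_newick("(((a:1,b:1)0.5:1,c:1)0.62:1,d:1,e:1);")
  c2 <- condense_tree(t2, 0.5)
  expect_equal(c2$meta$n_collapsed, 0)
  expect_equal(nrow(c2$phylo$edge), nrow(t2$phylo$edge))

  # all strong supports: unchanged; idempotence
  t3 <- gh2arch:::parse_newick("(((a:1,b:1)1:1,c:1)1:1,d:1,e:1);")
  expect_equal(condense_tree(t3, 0.5)$meta$n_collapsed, 0)
  cc <- condense_tree(c1, 0.5)
  expect_equal(cc$meta$n_collapsed, 0)
  expect_equal(nrow(cc$phylo$edge), nrow(c1$phylo$edge))
})

test_that("concordance reports monophyly, purity and nesting from labeled trees", {
  t1 <- gh2arch:::parse_newick("(((a1:1,a2:1):1,(b1:1,b2:1):1):1,c1:1,c2:1);")
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  cc <- concordance(t1, lab)
  expect_true(all(cc$per_label$monophyletic))
  expect_equal(cc$per_label$purity, rep(1, 3))

  # B planted inside the A clade: A impure, B nested within A's clade
  t2 <- gh2arch:::parse_newick(
    "(((a1:1,(b1:1,b2:1):1):1,a2:1):1,c1:1,c2:1);")
  cc2 <- concordance(t2, lab)
  pa <- cc2$per_label
  expect_false(pa$monophyletic[pa$label == "A"])
  expect_true(pa$monophyletic[pa$label == "B"])
  expect_lt(pa$purity[pa$label == "A"], 1)
  nest <- cc2$nesting
  expect_true(nest$nested[nest$inner == "B" & nest$outer == "A"])

  # singleton label is monophyletic by convention
  lab3 <- c(lab[1:5], c2 = "D")
  cc3 <- concordance(t1, lab3)
  expect_true(cc3$per_label$monophyletic[cc3$per_label$label == "D"])

  expect_error(concordance(t1, lab[1:4]), "unlabeled")
})

test_that("subcluster selection honors quotas, determinism and per-cluster coverage", {
  set.seed(702)
  # two tight clusters far apart
  D <- as.matrix(dist(c(rnorm(4, 0, 0.05), rnorm(4, 10, 0.05))))
  ids <- sprintf("s%d", 1:8)
  dimnames(D) <- list(ids, ids)
  sel <- subcluster_and_select(D, h = 1, quota = 3, seed = 21)
  expect_equal(length(unique(sel$subcluster)), 2)
  picked <- sel$seq_id[sel$selected]
  expect_true(all(c(any(picked %in% ids[1:4]), any(picked %in% ids[5:8]))))
  sel2 <- subcluster_and_select(D, h = 1, quota = 3, seed = 21)
  expect_equal(sel, sel2, ignore_attr = TRUE)

  all_sel <- subcluster_and_select(D, h = 1, quota = 99, seed = 21)
  expect_true(all(all_sel$selected))
  expect_true(attr(all_sel, "quota_truncated"))
})
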
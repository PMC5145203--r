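test_that("identical config and seed give byte-identical emitted datasets", {
  cfg <- synth_config(seed = 91, n_taxa = 20, dropout = 0.05, jitter = 0.03,
                      hybrid_count = 1, duplicate_gh2c_count = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(simulate_gh2(cfg), d1)
  emit_dataset(simulate_gh2(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("random trees have the expected size and are seed-deterministic", {
  t1 <- sample_tree(50, seed = 92)
  expect_equal(length(t1$phylo$tip.label), 50)
  # unrooted edge count 2n-3 (rooted binary has 2n-2 edges, one pair basal)
  expect_equal(nrow(ape::unroot(t1$phylo)$edge), 2 * 50 - 3)
  t2 <- sample_tree(50, seed = 92)
  expect_equal(ape::write.tree(t1$phylo), ape::write.tree(t2$phylo))
  t3 <- sample_tree(3, seed = 1)
  expect_equal(nrow(ape::unroot(t3$phylo)$edge), 3)
})

test_that("zero substitution rate propagates the root sequence to every leaf", {
  tr <- sample_tree(8, seed = 93)
  root <- random_protein(100)
  leaves <- evolve_sequences(tr, root, rate = 0)
  expect_true(all(leaves == root))
  msa <- as_msa(leaves)
  expect_true(all(p_distance(msa)$p == 0))
})

test_that("planted columns stay invariant inside the designated clade at high rates", {
  cfg <- synth_config(seed = 94, rate = 0.3)
  sim <- simulate_gh2(cfg)
  g <- gh2c_sequences(sim$sequences, sim$truth_hits)
  inclade <- g$residues[g$id %in% sim$planted$clade_records]
  expect_gte(length(inclade), 2)
  for (pos in sim$planted$positions) {
    expect_length(unique(substr(inclade, pos, pos)), 1)
  }
  # and the sequences do vary at unplanted positions
  expect_gt(length(unique(inclade)), 1)
})

test_that("expected divergence grows with path length", {
  tr <- gh2arch:::parse_newick("((a:0.05,b:0.05):0.8,(c:0.05,d:0.05):0.8);")
  pa <- numeric(30); pc <- numeric(30)
  set.seed(95)
  for (r in 1:30) {
    leaves <- evolve_sequences(tr, random_protein(200), rate = 0.5)
    msa <- as_msa(leaves)
    p <- p_distance(msa)$p
    pa[r] <- p["a", "b"]   # short path
    pc[r] <- p["a", "c"]   # long path
  }
  expect_lt(mean(pa), mean(pc))
})

test_that("the default scenario paints all five DA types with bicistronic splits", {
  sim <- simulate_gh2(synth_config(seed = 96))
  expect_setequal(unique(sim$truth$da_type),
                  c("1", "2", "3", "4", "5", "lacM"))
  # each bicistronic leaf yields two records with a recorded partnership
  t2 <- sim$truth[sim$truth$da_type == "2", ]
  expect_gt(nrow(t2), 0)
  for (i in seq_len(nrow(t2))) {
    expect_true(t2$partner[i] %in% sim$sequences$id)
    expect_equal(sim$truth$da_type[sim$truth$seq_id == t2$partner[i]],
                 "lacM")
  }
  # type-2 leaves sit inside the type-3-like clade of the true tree
  sets <- gh2arch:::clade_sets(sim$tree$phylo)
  members3like <- sort(sim$truth$seq_id[sim$truth$da_type %in% c("2", "3")])
  expect_true(any(vapply(sets, function(s) all(members3like %in% s) &&
                           length(s) == length(members3like), TRUE)))
})

test_that("zero-noise annotations equal the recorded truth; noise is applied after", {
  cfg0 <- synth_config(seed = 97, n_taxa = 25)
  sim0 <- simulate_gh2(cfg0)
  expect_equal(sim0$hits, sim0$truth_hits)

  cfgn <- synth_config(seed = 97, n_taxa = 25, dropout = 0.1, jitter = 0.05)
  simn <- simulate_gh2(cfgn)
  expect_equal(simn$truth_hits, sim0$truth_hits)
  expect_lt(nrow(simn$hits), nrow(simn$truth_hits))
  expect_true(all(simn$hits$model_coverage >= 0 &
                    simn$hits$model_coverage <= 1))
})

test_that("contaminant counts translate into exact filter rejections", {
  cfg <- synth_config(seed = 98, duplicate_gh2c_count = 4, hybrid_count = 3)
  sim <- simulate_gh2(cfg)
  flt <- filter_gh2c(sim$hits)
  expect_equal(sum(flt$reason == "multiple_gh2c", na.rm = TRUE), 4)
  expect_equal(sum(flt$reason == "hybrid_catalytic", na.rm = TRUE), 3)
})

test_that("classification recovers the planted truth perfectly without noise", {
  sim <- simulate_gh2(synth_config(seed = 99))
  calls <- gh2_classify(sim$sequences, sim$hits, companion = sim$partners)
  truth <- sim$truth[sim$truth$da_type != "lacM", ]
  merged <- merge(as.data.frame(calls)[, c("seq_id", "da_type")],
                  truth[, c("seq_id", "da_type")], by = "seq_id")
  expect_equal(nrow(merged), nrow(truth))
  expect_true(all(merged$da_type.x == merged$da_type.y))
})
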
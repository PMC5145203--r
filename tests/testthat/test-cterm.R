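cfg <- gh2_config()

test_that("C-terminal extensions are the residue tail past the last identified domain", {
  set.seed(501)
  s <- random_protein(1000)
  seqs <- mk_seqs(s1 = s)
  arch <- tibble::tibble(seq_id = "s1", element = "GH2C", start = 500L,
                         end = 800L, seq_length = 1000L)
  ext <- extract_ct_extensions(arch, seqs, cfg)
  expect_equal(ext$start, 801L)
  expect_equal(ext$length, 200L)
  expect_equal(ext$residues, substr(s, 801, 1000))

  # domain runs to the terminus: nothing to extract
  arch2 <- dplyr::mutate(arch, end = 1000L)
  expect_equal(nrow(extract_ct_extensions(arch2, seqs, cfg)), 0)

  # 59-residue tail sits below the 60-residue floor
  arch3 <- dplyr::mutate(arch, end = 941L)
  expect_equal(nrow(extract_ct_extensions(arch3, seqs, cfg)), 0)
  arch4 <- dplyr::mutate(arch, end = 940L)
  expect_equal(extract_ct_extensions(arch4, seqs, cfg)$length, 60L)
})

mutate_at_positions <- function(s, pos) {
  cc <- strsplit(s, "")[[1]]
  for (i in pos) cc[i] <- setdiff(c("A", "G"), cc[i])[1]
  paste(cc, collapse = "")
}

test_that("BIG1 tagging applies both strict thresholds against the reference", {
  set.seed(502)
  ref <- tibble::tibble(id = "BIG1_ref", residues = random_protein(20))
  # identity exactly 0.40 (8/20 mismatches): strict bound excludes it
  r40 <- mutate_at_positions(ref$residues, 1:12)
  # identity 0.45
  r45 <- mutate_at_positions(ref$residues, 1:11)
  regions <- tibble::tibble(seq_id = c("x40", "x45", "xid"),
                            residues = c(r40, r45, ref$residues))
  tags <- tag_big1(regions, ref, cfg)
  expect_equal(tags$big1, c(FALSE, TRUE, TRUE))
  expect_equal(tags$best_identity[tags$seq_id == "xid"], 1.0)
  expect_equal(tags$best_coverage[tags$seq_id == "xid"], 1.0)

  # high identity but low reference coverage: not tagged
  half <- substr(ref$residues, 1, 10)
  tag_half <- tag_big1(tibble::tibble(seq_id = "h", residues = half), ref, cfg)
  expect_false(tag_half$big1)
  expect_lte(tag_half$best_coverage, 0.6)

  expect_error(tag_big1(regions, ref[0, ], cfg), "reference")
})

test_that("BIG1 tagging is monotone in both thresholds", {
  set.seed(503)
  ref <- tibble::tibble(id = "r", residues = random_protein(30))
  regions <- tibble::tibble(
    seq_id = sprintf("q%d", 1:6),
    residues = vapply(c(0, 5, 10, 15, 20, 25), function(k) {
      mutate_at_positions(ref$residues, seq_len(k))
    }, ""))
  base <- tag_big1(regions, ref, cfg)
  loose <- tag_big1(regions, ref, gh2_config(big1_min_identity = 0.2,
                                             big1_min_coverage = 0.3))
  expect_true(all(loose$big1 >= base$big1))
})

test_that("extension clustering partitions by band then by single linkage", {
  set.seed(504)
  blockP <- random_protein(40); blockQ <- random_protein(40)
  blockR <- random_protein(40); blockS <- random_protein(40)
  blockT <- random_protein(40); blockU <- random_protein(40)
  # (a,b) and (b,c) share half their residues; (a,c) share none; the twin
  # pair shares nothing with the chain
  ext <- tibble::tibble(
    seq_id = c("a", "b", "c", "far", "twin1", "twin2"),
    start = 1L,
    residues = c(paste0(blockP, blockQ), paste0(blockQ, blockR),
                 paste0(blockR, blockS), random_protein(900),
                 paste0(blockT, blockU), paste0(blockT, blockU)),
    length = c(80L, 80L, 80L, 900L, 80L, 80L))
  cl <- cluster_extensions(ext, cfg)
  expect_equal(nrow(cl), 6)
  # every extension in exactly one cluster
  expect_equal(anyDuplicated(cl$seq_id), 0)
  # band separation
  expect_equal(cl$band[cl$seq_id == "far"], 2L)
  expect_true(all(cl$band[cl$seq_id != "far"] == 1L))
  # transitive closure: a-b-c chained into one cluster
  abc <- unique(cl$cluster[cl$seq_id %in% c("a", "b", "c")])
  expect_length(abc, 1)
  twins <- unique(cl$cluster[cl$seq_id %in% c("twin1", "twin2")])
  expect_length(twins, 1)
  expect_false(abc == twins)
})

test_that("single-linkage clusters equal brute-force graph components", {
  set.seed(505)
  for (rep in 1:5) {
    base <- random_protein(50)
    n <- sample(3:6, 1)
    resid <- vapply(seq_len(n), function(i) {
      mutate_at_positions(base, sample(50, sample(c(5, 20, 35, 45), 1)))
    }, "")
    ext <- tibble::tibble(seq_id = sprintf("e%d", seq_len(n)), start = 1L,
                          residues = resid, length = 50L)
    cfg_wide <- gh2_config(ct_length_bands = list(c(1, 100)))
    cl <- cluster_extensions(ext, cfg_wide)
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      al <- nw_align(resid[i], resid[j])
      idm[i, j] <- idm[j, i] <- percent_identity(al, "shorter_seq")
    }
    oracle <- brute_components(idm, cfg_wide$ct_id_threshold)
    got <- as.integer(factor(cl$cluster[match(ext$seq_id, cl$seq_id)]))
    # same partition up to relabeling
    expect_equal(length(unique(oracle)), length(unique(got)))
    for (g in unique(got)) {
      expect_length(unique(oracle[got == g]), 1)
    }
  }
})

test_that("type-5 subtyping separates BIG1-bearing, modular, and plain extensions", {
  calls <- tibble::tibble(seq_id = c("b", "m", "p", "none"), da_type = "5",
                          subtype = "5-unassigned", evidence = "e",
                          flags = "")
  arch <- dplyr::bind_rows(
    tibble::tibble(seq_id = "m", element = c("GH2C", "DUF4982", "F5_F8_type_C"),
                   start = c(1L, 400L, 520L), end = c(390L, 500L, 640L),
                   seq_length = 900L),
    tibble::tibble(seq_id = c("b", "p", "none"), element = "DUF4982",
                   start = 400L, end = 500L, seq_length = 900L))
  ext <- tibble::tibble(seq_id = c("b", "p"), start = 501L,
                        residues = "X", length = 300L)
  tags <- tibble::tibble(seq_id = "b", big1 = TRUE, best_identity = 0.6,
                         best_coverage = 0.9, best_reference = "r")
  out <- subtype_type5(calls, tags, arch, ext, cfg)
  expect_equal(out$subtype, c("5-BIG1", "5-modular", "5-Cter",
                              "5-unassigned"))
})
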
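cfg <- gh2_config()

test_that("the GH2C selection filter applies the single-domain and coverage rules", {
  expect_equal(filter_gh2c(mk_hits(list("s", "GH2C", 1, 300, 0.69)),
                           cfg)$reason, "low_coverage")
  # boundary inclusive: at least 70% passes
  expect_true(filter_gh2c(mk_hits(list("s", "GH2C", 1, 300, 0.70)), cfg)$pass)
  expect_equal(filter_gh2c(mk_hits(list("s", "GH2C", 1, 300, 0.95),
                                   list("s", "GH2C", 400, 700, 0.95)),
                           cfg)$reason, "multiple_gh2c")
  expect_equal(filter_gh2c(mk_hits(list("s", "Bgal_Small_N", 1, 200, 0.9)),
                           cfg)$reason, "no_gh2c")
  expect_equal(filter_gh2c(mk_hits(list("s", "GH2C", 1, 300, 0.9),
                                   list("s", "PKinase", 400, 600, 0.9)),
                           cfg)$reason, "hybrid_catalytic")
})

test_that("raising the coverage threshold never increases the pass count", {
  set.seed(401)
  hits <- dplyr::bind_rows(lapply(1:40, function(i) {
    mk_hits(list(sprintf("s%02d", i), "GH2C", 1, 300, runif(1, 0.5, 1)))
  }))
  passes <- vapply(seq(0.5, 1, by = 0.05), function(th) {
    sum(filter_gh2c(hits, gh2_config(min_gh2c_coverage = th))$pass)
  }, 1)
  expect_true(all(diff(passes) <= 0))
})

arch_row <- function(seq_id, els, starts, ends, L) {
  tibble::tibble(seq_id = seq_id, element = els, start = as.integer(starts),
                 end = as.integer(ends), seq_length = as.integer(L))
}

test_that("core detection distinguishes canonical, GH2d-sized gap, and incomplete", {
  canonical <- arch_row("s", c("GH2N", "GH2d", "GH2C"),
                        c(1, 190, 520), c(180, 500, 840), 900)
  expect_equal(detect_core(canonical, cfg, 300)$layout, "canonical")

  # gap of 309 residues with reference length 300 and window 0.7-1.3
  gap <- arch_row("s", c("GH2N", "GH2C"), c(1, 490), c(180, 800), 850)
  expect_equal(detect_core(gap, cfg, 300)$layout, "gh2d_like_gap")

  only_c <- arch_row("s", "GH2C", 1, 320, 400)
  expect_equal(detect_core(only_c, cfg, 300)$layout, "incomplete")
})

test_that("the five-way decision order assigns DA types with evidence", {
  core <- list(els = c("GH2N", "GH2d", "GH2C"),
               starts = c(1, 190, 520), ends = c(180, 500, 840))
  # canonical type 3: linker + small subunit downstream
  a3 <- arch_row("s3", c(core$els, "DUF4981", "Bgal_Small_N"),
                 c(core$starts, 850, 960), c(core$ends, 950, 1180), 1180)
  c3 <- classify_da(a3, cfg, 300)
  expect_equal(c3$da_type, "3")
  expect_equal(c3$subtype, "3-canonical")
  expect_match(c3$evidence, "Bgal_Small_N")

  # type 5: DUF4982 immediately downstream plus a long unannotated tail
  a5 <- arch_row("s5", c(core$els, "DUF4982"), c(core$starts, 850),
                 c(core$ends, 940), 1190)
  expect_equal(classify_da(a5, cfg, 300)$da_type, "5")

  # type 4: bare unannotated 200-residue tail
  a4 <- arch_row("s4", core$els, core$starts, core$ends, 1040)
  expect_equal(classify_da(a4, cfg, 300)$da_type, "4")

  # 30-residue tail is below the 60-residue floor: core-only, pending
  a12 <- arch_row("s12", core$els, core$starts, core$ends, 870)
  expect_equal(classify_da(a12, cfg, 300)$da_type, "1or2")

  # small subunit wins over DUF4982 when both occur
  a35 <- arch_row("s35", c(core$els, "DUF4982", "Bgal_Small_N"),
                  c(core$starts, 850, 960), c(core$ends, 940, 1180), 1400)
  expect_equal(classify_da(a35, cfg, 300)$da_type, "3")

  # N-terminal decorations are flags, never the type
  adec <- arch_row("sd", c("YSIRK_signal", core$els, "DUF4981",
                           "Bgal_Small_N"),
                   c(1, core$starts + 60, 910, 1020),
                   c(50, core$ends + 60, 1010, 1240), 1240)
  cdec <- classify_da(adec, cfg, 300)
  expect_equal(cdec$da_type, "3")
  expect_match(cdec$flags, "YSIRK")

  # replaced-linker subtype when DUF4981 is absent
  a3r <- arch_row("s3r", c(core$els, "Bgal_Small_N"),
                  c(core$starts, 960), c(core$ends, 1180), 1180)
  expect_equal(classify_da(a3r, cfg, 300)$subtype, "3-replaced")
})

test_that("bicistronic resolution uses partners and tagged subclusters, defaulting to type 1", {
  calls <- tibble::tibble(seq_id = c("a", "b", "c", "d"),
                          da_type = "1or2", subtype = "1or2",
                          evidence = "core", flags = "")
  companion <- tibble::tibble(seq_id = c("a", "c", "d"),
                              partner = c("a_M", NA, "ghost"),
                              subcluster = c(NA, "4", NA))
  expect_warning(
    out <- resolve_bicistronic(calls, companion,
                               bicistronic_subclusters = "4",
                               known_ids = c("a", "a_M", "b", "c", "d")),
    "companion id not found")
  expect_equal(out$da_type, c("2", "1", "2", "1"))
  expect_warning(
    resolve_bicistronic(calls[4, ], companion,
                        known_ids = c("a", "b", "c", "d")),
    "companion id not found")
})

test_that("every filtered sequence receives exactly one DA type end to end", {
  sim <- simulate_gh2(synth_config(seed = 77, n_taxa = 30))
  calls <- gh2_classify(sim$sequences, sim$hits, cfg, sim$partners)
  expect_equal(nrow(calls), nrow(sim$sequences))
  expect_true(all(calls$da_type %in% c("1", "2", "3", "4", "5",
                                       "unassigned", "rejected")))
  assigned <- calls[calls$da_type != "rejected", ]
  expect_true(all(nchar(assigned$evidence) > 0))
})

test_that("DA-type tallies from a written report reproduce the in-memory counts", {
  sim <- simulate_gh2(synth_config(seed = 78, n_taxa = 30))
  calls <- gh2_classify(sim$sequences, sim$hits, cfg, sim$partners)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_da_report(calls, f)
  back <- read_da_report(f)
  expect_equal(tally_da_types(back), tally_da_types(calls))
})
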
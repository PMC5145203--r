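test_that("architecture building sorts N-to-C and preserves tandem repeats", {
  h <- mk_hits(list("s1", "GH2C", 310, 620, 0.95),
               list("s1", "GH2N", 1, 180, 0.9),
               list("s1", "GH2d", 190, 300, 0.9))
  a <- build_architecture(h, 700)
  expect_equal(a$element, c("GH2N", "GH2d", "GH2C"))

  h2 <- mk_hits(list("s2", "A", 10, 60, 0.9), list("s2", "A", 100, 150, 0.9))
  a2 <- build_architecture(h2, 200)
  expect_equal(a2$element, c("A", "A"))

  expect_equal(nrow(build_architecture(mk_hits(), 100)), 0)
})

test_that("overlapping hits resolve to the higher-coverage model", {
  # overlap 41/41 of the shorter span B, > 50%: B is discarded
  h <- mk_hits(list("s1", "A", 10, 100, 0.9), list("s1", "B", 50, 90, 0.5))
  expect_equal(build_architecture(h, 150)$element, "A")
  # mild overlap below half the shorter span: both kept
  h2 <- mk_hits(list("s1", "A", 10, 100, 0.9), list("s1", "B", 85, 150, 0.5))
  expect_equal(build_architecture(h2, 150)$element, c("A", "B"))
  # coverage tie resolved toward the longer span
  h3 <- mk_hits(list("s1", "A", 10, 100, 0.8), list("s1", "B", 10, 60, 0.8))
  expect_equal(build_architecture(h3, 150)$element, "A")
})

test_that("vocabulary slots follow median relative position with repeat ordinals", {
  arch <- dplyr::bind_rows(
    tibble::tibble(seq_id = "s1", element = c("A", "B"),
                   start = c(1L, 101L), end = c(80L, 180L), seq_length = 200L),
    tibble::tibble(seq_id = "s2", element = c("A", "A", "B"),
                   start = c(1L, 81L, 161L), end = c(60L, 140L, 220L),
                   seq_length = 240L))
  v <- build_vocabulary(arch)
  expect_equal(v$slot, c("A_1", "A_2", "B_1"))

  one <- tibble::tibble(seq_id = "s1", element = c("GH2N", "GH2d", "GH2C"),
                        start = c(1L, 200L, 520L), end = c(180L, 500L, 840L),
                        seq_length = 900L)
  expect_equal(build_vocabulary(one)$slot, c("GH2N_1", "GH2d_1", "GH2C_1"))
})

test_that("vocabulary is invariant to the input order of architectures", {
  set.seed(301)
  arch <- random_architectures(40)
  v1 <- build_vocabulary(arch)
  ids <- unique(arch$seq_id)
  for (s in 1:5) {
    perm <- sample(ids)
    arch2 <- arch[order(match(arch$seq_id, perm)), ]
    expect_equal(build_vocabulary(arch2), v1)
  }
})

test_that("encoding sets presence and repeat bits; decoding inverts exactly", {
  arch <- dplyr::bind_rows(
    tibble::tibble(seq_id = "s1", element = c("A", "B"),
                   start = c(1L, 101L), end = c(80L, 180L), seq_length = 200L),
    tibble::tibble(seq_id = "s2", element = c("A", "A", "B"),
                   start = c(1L, 81L, 161L), end = c(60L, 140L, 220L),
                   seq_length = 240L))
  v <- build_vocabulary(arch)
  enc <- encode_architectures(arch, v)
  expect_equal(unlist(enc[enc$seq_id == "s1", v$slot]),
               c(A_1 = 1L, A_2 = 0L, B_1 = 1L))
  expect_equal(unlist(enc[enc$seq_id == "s2", v$slot]),
               c(A_1 = 1L, A_2 = 1L, B_1 = 1L))
  dec <- decode_vector(enc[enc$seq_id == "s2", v$slot], v)
  expect_equal(dec$count[dec$domain == "A"], 2L)
  expect_equal(dec$count[dec$domain == "B"], 1L)

  # empty architecture encodes to the all-zero vector
  enc0 <- encode_architectures(arch, v, ids = c("s1", "s2", "s0"))
  expect_equal(sum(unlist(enc0[enc0$seq_id == "s0", v$slot])), 0L)

  # out-of-vocabulary element is a hard error naming the slot
  bad <- tibble::tibble(seq_id = "sx", element = "Z", start = 1L, end = 50L,
                        seq_length = 100L)
  expect_error(encode_architectures(dplyr::bind_rows(arch, bad), v), "Z_1")
})

test_that("encode/decode round-trips random architectures and keeps repeat bits monotone", {
  set.seed(302)
  arch <- random_architectures(300)
  v <- build_vocabulary(arch)
  enc <- encode_architectures(arch, v)
  counts <- dplyr::count(arch, seq_id, element)
  for (sid in enc$seq_id) {
    dec <- decode_vector(enc[enc$seq_id == sid, v$slot], v)
    truth <- counts[counts$seq_id == sid, ]
    expect_equal(dec$count[order(dec$domain)],
                 truth$n[order(truth$element)], ignore_attr = TRUE)
  }
  # monotone repeat bits, checked across the whole matrix
  for (d in unique(v$domain)) {
    slots <- v$slot[v$domain == d]
    if (length(slots) < 2) next
    m <- as.matrix(enc[, slots])
    expect_true(all(m[, -ncol(m), drop = FALSE] >=
                      m[, -1, drop = FALSE]))
  }
})
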
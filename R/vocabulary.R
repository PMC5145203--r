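#' Build the repeat-aware domain vocabulary
#'
#' Defines one binary-vector slot per (domain, occurrence ordinal) pair, up
#' to the maximum tandem-repeat count observed in the dataset. Slots are
#' ordered by the median relative position of the domain across the dataset
#' (envelope midpoint divided by sequence length, so the vector reads roughly
#' N- to C-terminal), with ties broken alphabetically and ordinals ascending
#' within a domain. The ordering depends only on the set of architectures,
#' not on their input order.
#'
#' @param architectures Long architecture tibble from [build_architectures()].
#' @return Tibble with columns `domain`, `ordinal`, `slot` (label
#'   `"<domain>_<ordinal>"`), in canonical slot order.
#' @export
build_vocabulary <- function(architectures) {
  if (!nrow(architectures)) abort("need at least one non-empty architecture")
  pos <- architectures |>
    group_by(.data$element) |>
    summarise(
      mid = median((.data$start + .data$end) / 2 / .data$seq_length),
      .groups = "drop"
    )
  reps <- architectures |>
    count(.data$seq_id, .data$element) |>
    group_by(.data$element) |>
    summarise(max_rep = max(.data$n), .groups = "drop")
  left_join(pos, reps, by = "element") |>
    arrange(.data$mid, .data$element) |>
    purrr::pmap(function(element, mid, max_rep) {
      tibble(domain = element, ordinal = seq_len(max_rep))
    }) |>
    bind_rows() |>
    mutate(slot = paste0(.data$domain, "_", .data$ordinal))
}

#' Encode architectures as binary domain-architecture vectors
#'
#' Bit `(d, k)` is 1 iff the sequence carries at least `k` occurrences of
#' domain `d`; consequently bit `(d, k) = 1` implies bit `(d, k-1) = 1`.
#'
#' @param architectures Long architecture tibble. Sequences present in the
#'   tibble but with domains missing from `vocabulary` raise an error naming
#'   the offending slot.
#' @param vocabulary Tibble from [build_vocabulary()].
#' @param ids Sequence ids to encode; defaults to the ids present in
#'   `architectures`. Ids without any element get the all-zero vector.
#' @return Wide tibble: `seq_id` plus one 0/1 integer column per slot, in
#'   vocabulary order.
#' @export
encode_architectures <- function(architectures, vocabulary,
                                 ids = unique(architectures$seq_id)) {
  counts <- count(architectures, .data$seq_id, .data$element)
  missing <- counts |>
    left_join(
      vocabulary |> group_by(.data$domain) |>
        summarise(max_rep = max(.data$ordinal), .groups = "drop"),
      by = c(element = "domain")
    ) |>
    filter(is.na(.data$max_rep) | .data$n > .data$max_rep)
  if (nrow(missing)) {
    abort(paste0(
      "architecture element(s) outside the vocabulary: ",
      paste(sprintf("%s_%d (%s)", missing$element,
                    ifelse(is.na(missing$max_rep), 1L, missing$n),
                    missing$seq_id),
            collapse = ", ")))
  }
  counts <- filter(counts, .data$seq_id %in% ids)
  cnt <- matrix(0L, length(ids), nrow(vocabulary),
                dimnames = list(ids, vocabulary$slot))
  for (r in seq_len(nrow(counts))) {
    k <- which(vocabulary$domain == counts$element[r] &
                 vocabulary$ordinal <= counts$n[r])
    cnt[counts$seq_id[r], k] <- 1L
  }
  out <- as_tibble(cnt)
  dplyr::bind_cols(tibble(seq_id = ids), out)
}

#' Decode a binary vector back to a domain multiset
#'
#' Inverse of [encode_architectures()] up to element order: returns the
#' occurrence counts implied by the set bits, validating the
#' monotone-repeat-bit invariant.
#'
#' @param bits Named 0/1 vector (names = slot labels) or a one-row slice of
#'   the encoded tibble (without `seq_id`).
#' @param vocabulary Tibble from [build_vocabulary()].
#' @return Tibble with columns `domain`, `count` (domains with count 0
#'   omitted).
#' @export
decode_vector <- function(bits, vocabulary) {
  b <- as.integer(unlist(bits))
  if (length(b) != nrow(vocabulary)) {
    abort("vector length does not match vocabulary size")
  }
  tab <- vocabulary |> mutate(bit = b)
  bad <- tab |>
    group_by(.data$domain) |>
    summarise(mono = all(diff(.data$bit[order(.data$ordinal)]) <= 0),
              .groups = "drop") |>
    filter(!.data$mono)
  if (nrow(bad)) {
    abort(paste0("non-monotone repeat bits for domain(s): ",
                 paste(bad$domain, collapse = ", ")))
  }
  tab |>
    group_by(.data$domain) |>
    summarise(count = sum(.data$bit), .groups = "drop") |>
    filter(.data$count > 0) |>
    arrange(.data$domain)
}

#' Export the binary-vector matrix
#'
#' Tab-separated, header row of slot labels, one row per sequence.
#'
#' @param vectors Encoded tibble from [encode_architectures()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_da_vectors <- function(vectors, path) {
  readr::write_tsv(vectors, path)
  invisible(path)
}
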
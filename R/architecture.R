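#' Build a domain architecture for one sequence
#'
#' Orders a sequence's domain hits N-terminus to C-terminus and resolves
#' heavily overlapping hits, which in Pfam-style annotation almost always
#' reflect competing models for the same region. Two hits conflict when their
#' envelope overlap exceeds `overlap_fraction` (default 0.5) of the shorter
#' span; the hit with the higher model coverage wins (ties: longer span, then
#' lexicographically smaller domain name). Tandem repeats of a domain are
#' kept as repeated elements.
#'
#' @param hits Domain hits for a single sequence.
#' @param seq_length Length of the protein in residues.
#' @param config A [gh2_config()].
#' @return Tibble with columns `seq_id`, `element`, `start`, `end`,
#'   `seq_length`, ordered by `start`. Zero rows for an empty hit list.
#' @export
build_architecture <- function(hits, seq_length, config = gh2_config()) {
  empty <- tibble(seq_id = character(), element = character(),
                  start = integer(), end = integer(), seq_length = integer())
  if (!nrow(hits)) return(empty)
  if (length(unique(hits$seq_id)) != 1) {
    abort("build_architecture() expects hits of a single sequence")
  }
  validate_hits(hits)
  if (any(hits$env_end > seq_length)) {
    abort("envelope end beyond sequence length")
  }
  # priority: coverage desc, span desc, name asc; greedy acceptance
  span <- hits$env_end - hits$env_start + 1
  ord <- order(-hits$model_coverage, -span, hits$domain)
  keep <- integer(0)
  for (i in ord) {
    conflict <- FALSE
    for (j in keep) {
      ov <- min(hits$env_end[i], hits$env_end[j]) -
        max(hits$env_start[i], hits$env_start[j]) + 1
      if (ov > config$overlap_fraction * min(span[i], span[j])) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) keep <- c(keep, i)
  }
  keep <- keep[order(hits$env_start[keep], hits$env_end[keep])]
  tibble(seq_id = hits$seq_id[keep], element = hits$domain[keep],
         start = as.integer(hits$env_start[keep]),
         end = as.integer(hits$env_end[keep]),
         seq_length = as.integer(seq_length))
}

#' Build architectures for a whole annotation set
#'
#' @param hits Domain-hit tibble (any number of sequences).
#' @param seqs Sequence tibble from [read_fasta()]; provides lengths and the
#'   universe of sequence ids (sequences without hits get empty
#'   architectures, i.e. no rows).
#' @param config A [gh2_config()].
#' @return A long tibble, one row per retained domain element.
#' @export
build_architectures <- function(hits, seqs, config = gh2_config()) {
  validate_hits(hits, seqs)
  len <- setNames(nchar(seqs$residues), seqs$id)
  hits |>
    dplyr::group_split(.data$seq_id) |>
    purrr::map(function(h) {
      build_architecture(h, len[[h$seq_id[1]]], config)
    }) |>
    bind_rows()
}
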
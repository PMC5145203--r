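#' Extract unannotated C-terminal extensions
#'
#' Returns the residue stretch downstream of the last identified domain for
#' every sequence whose tail is at least `min_ct_extension` residues long
#' (default 60, the smallest extension treated as meaningful).
#'
#' @param architectures Long architecture tibble.
#' @param seqs Sequence tibble.
#' @param config A [gh2_config()].
#' @return Tibble with columns `seq_id`, `start` (1-based index of the first
#'   extension residue), `residues`, `length`. Sequences without a
#'   qualifying extension are absent.
#' @export
extract_ct_extensions <- function(architectures, seqs,
                                  config = gh2_config()) {
  last_end <- architectures |>
    group_by(.data$seq_id) |>
    summarise(last_end = max(.data$end), .groups = "drop")
  seqs |>
    dplyr::inner_join(last_end, by = c(id = "seq_id")) |>
    mutate(start = .data$last_end + 1L,
           length = nchar(.data$residues) - .data$last_end) |>
    filter(.data$length >= config$min_ct_extension) |>
    mutate(residues = substr(.data$residues, .data$start,
                             nchar(.data$residues))) |>
    select(seq_id = "id", "start", "residues", "length")
}

#' Tag BIG1-like modules in C-terminal regions
#'
#' A region is tagged BIG1 when, against at least one reference BIG1 module,
#' the global-alignment identity exceeds `big1_min_identity` (default 0.40,
#' strict) and the aligned coverage of the reference exceeds
#' `big1_min_coverage` (default 0.60, strict). Identity is matches divided
#' by aligned reference positions; coverage is aligned reference positions
#' divided by the reference length — both denominators defined against the
#' reference exemplar. Lowering either bound can only add tags, never remove
#' one.
#'
#' @param regions Tibble with `seq_id`, `residues` (the candidate regions).
#' @param references Tibble with `id`, `residues`: BIG1 reference modules
#'   (at least one).
#' @param config A [gh2_config()] (thresholds, scoring scheme penalties).
#' @param scheme A [scoring_scheme()].
#' @return Tibble with columns `seq_id`, `big1` (logical), `best_identity`,
#'   `best_coverage`, `best_reference`.
#' @export
tag_big1 <- function(regions, references, config = gh2_config(),
                     scheme = scoring_scheme(gap_open = config$gap_open,
                                             gap_extend = config$gap_extend)) {
  if (is.null(references) || !nrow(references)) {
    abort("tag_big1() requires at least one BIG1 reference module")
  }
  stopifnot(all(nchar(regions$residues) >= 1))
  purrr::pmap(regions[, c("seq_id", "residues")], function(seq_id, residues) {
    stats <- purrr::map2(references$id, references$residues, function(rid, rres) {
      al <- nw_align(residues, rres, scheme)
      cov <- alignment_ref_coverage(al)
      tibble(reference = rid,
             identity = if (cov$aligned_ref == 0) 0 else
               percent_identity(al, "reference_positions"),
             coverage = cov$aligned_ref / cov$ref_len)
    }) |> bind_rows()
    best <- stats |>
      arrange(desc(.data$identity), desc(.data$coverage), .data$reference) |>
      slice(1)
    tagged <- any(stats$identity > config$big1_min_identity &
                    stats$coverage > config$big1_min_coverage)
    tibble(seq_id = seq_id, big1 = tagged, best_identity = best$identity,
           best_coverage = best$coverage, best_reference = best$reference)
  }) |> bind_rows()
}

#' Cluster C-terminal extensions by length band and similarity
#'
#' Extensions are partitioned first into length bands, then single-linkage
#' clustered on pairwise global-alignment identity (shorter-sequence
#' denominator, so terminal overhangs dilute similarity): two extensions
#' join a cluster when a chain of pairs with
#' identity at or above `ct_id_threshold` (default 0.30) connects them —
#' the connected components of the thresholded identity graph. Labels are
#' deterministic: bands sorted ascending, clusters within a band ordered by
#' their smallest member id, labelled `Ct_<band>_<index>`.
#'
#' @param extensions Tibble from [extract_ct_extensions()].
#' @param config A [gh2_config()] (`ct_id_threshold`, `ct_length_bands`).
#' @param scheme A [scoring_scheme()].
#' @return Tibble with columns `seq_id`, `length`, `band`, `cluster`.
#'   Extensions outside every band are assigned band `NA` and cluster
#'   `"Ct_0_0"`.
#' @export
cluster_extensions <- function(extensions, config = gh2_config(),
                               scheme = scoring_scheme(
                                 gap_open = config$gap_open,
                                 gap_extend = config$gap_extend)) {
  stopifnot(nrow(extensions) >= 1)
  bands <- config$ct_length_bands
  band_of <- function(len) {
    for (b in seq_along(bands)) {
      if (len >= bands[[b]][1] && len <= bands[[b]][2]) return(b)
    }
    NA_integer_
  }
  ext <- extensions |>
    mutate(band = vapply(.data$length, band_of, 1L)) |>
    arrange(.data$seq_id)
  out <- ext |>
    dplyr::group_split(.data$band) |>
    purrr::map(function(g) {
      if (is.na(g$band[1])) {
        return(mutate(g, cluster = "Ct_0_0"))
      }
      comp <- if (nrow(g) == 1) 1L else {
        idm <- pairwise_identity_matrix(g$residues, scheme)
        hc <- hclust(as.dist(1 - idm), method = "single")
        cutree(hc, h = 1 - config$ct_id_threshold)
      }
      # renumber components by smallest member id
      first_id <- vapply(split(g$seq_id, comp), min, "")
      relabel <- setNames(rank(first_id, ties.method = "first"),
                          names(first_id))
      mutate(g, cluster = sprintf("Ct_%d_%d", .data$band,
                                  relabel[as.character(comp)]))
    }) |>
    bind_rows() |>
    select("seq_id", "length", "band", "cluster")
  out
}

pairwise_identity_matrix <- function(residues, scheme) {
  n <- length(residues)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- nw_align(residues[i], residues[j], scheme)
      m[i, j] <- m[j, i] <- percent_identity(al, "shorter_seq")
    }
  }
  m
}

#' Subtype DA type 5 sequences by their C-terminal composition
#'
#' Applies a small rule grammar over the presence of a BIG1 tag, further
#' identified modules downstream of the DUF4982 linker, and the unannotated
#' block: the two well-attested splits are BIG1-bearing (`5-BIG1`) versus
#' BIG1-free extensions (`5-Cter`), with module-decorated C-termini
#' reported as `5-modular`. Sequences without any extension record fall
#' back to `5-unassigned`.
#'
#' @param calls `gh2_calls` tibble (only `da_type == "5"` rows are
#'   relabelled).
#' @param big1_tags Tibble from [tag_big1()].
#' @param architectures Long architecture tibble.
#' @param extensions Tibble from [extract_ct_extensions()].
#' @param config A [gh2_config()].
#' @return `calls` with refined `subtype` for type-5 rows.
#' @export
subtype_type5 <- function(calls, big1_tags, architectures, extensions,
                          config = gh2_config()) {
  t5 <- which(calls$da_type == "5")
  for (i in t5) {
    id <- calls$seq_id[i]
    arch <- filter(architectures, .data$seq_id == id)
    duf_start <- arch$start[match(config$linker_type5, arch$element)]
    modular <- any(!is.na(duf_start)) &&
      any(arch$start > duf_start & arch$element != config$linker_type5,
          na.rm = TRUE)
    has_ext <- id %in% extensions$seq_id
    big1 <- id %in% big1_tags$seq_id[big1_tags$big1]
    calls$subtype[i] <- if (big1) "5-BIG1"
    else if (modular) "5-modular"
    else if (has_ext) "5-Cter"
    else "5-unassigned"
  }
  calls
}

#' Write the C-terminal cluster report
#'
#' Tab-separated: `seq_id`, extension length, cluster label, BIG1 tag, best
#' identity and coverage against the BIG1 references.
#'
#' @param clusters Tibble from [cluster_extensions()].
#' @param big1_tags Tibble from [tag_big1()] (optional).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ct_report <- function(clusters, big1_tags = NULL, path) {
  out <- clusters
  if (!is.null(big1_tags)) {
    out <- left_join(out, big1_tags, by = "seq_id")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
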
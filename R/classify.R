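#' Selection filter on the catalytic domain
#'
#' A sequence enters the analysis only if it carries exactly one catalytic
#' GH2C domain covering at least `min_gh2c_coverage` (default 0.70, boundary
#' inclusive) of the Pfam model, and no additional catalytic module from the
#' hybrid-enzyme blacklist (glycosyl transferases, lipases, kinases, ...).
#' Rejections carry the first failed rule.
#'
#' @param hits Domain hits for any number of sequences.
#' @param config A [gh2_config()].
#' @return Tibble with columns `seq_id`, `pass` (logical), `reason`
#'   (`NA` for passes; otherwise `no_gh2c`, `multiple_gh2c`, `low_coverage`
#'   or `hybrid_catalytic`).
#' @export
filter_gh2c <- function(hits, config = gh2_config()) {
  hits |>
    dplyr::group_split(.data$seq_id) |>
    purrr::map(function(h) {
      id <- h$seq_id[1]
      g <- filter(h, .data$domain == config$core_gh2c)
      reason <- if (nrow(g) == 0) "no_gh2c"
      else if (nrow(g) > 1) "multiple_gh2c"
      else if (g$model_coverage < config$min_gh2c_coverage) "low_coverage"
      else if (any(h$domain %in% config$catalytic_blacklist)) "hybrid_catalytic"
      else NA_character_
      tibble(seq_id = id, pass = is.na(reason), reason = reason)
    }) |>
    bind_rows()
}

#' Detect the three-domain core layout
#'
#' The canonical GH2 core is GH2N, GH2d, GH2C in N-to-C order. When GH2d is
#' absent but the unannotated stretch between the end of GH2N and the start
#' of GH2C has a length within `gh2d_gap_window` (default 0.7-1.3) times the
#' reference GH2d length, the sequence is taken to carry an equivalent,
#' Pfam-silent domain (`gh2d_like_gap`). Anything else is `incomplete`.
#'
#' @param architecture One sequence's architecture tibble.
#' @param config A [gh2_config()].
#' @param gh2d_ref_length Reference GH2d span; defaults to
#'   `config$gh2d_ref_length` (set it from the dataset median via
#'   [gh2_classify()]).
#' @return List with `layout` (one of `canonical`, `gh2d_like_gap`,
#'   `incomplete`) and `evidence` (character).
#' @export
detect_core <- function(architecture, config = gh2_config(),
                        gh2d_ref_length = config$gh2d_ref_length) {
  el <- architecture$element
  pos <- function(d) architecture$start[match(d, el)]
  has <- function(d) d %in% el
  if (has(config$core_gh2n) && has(config$core_gh2d) && has(config$core_gh2c) &&
      pos(config$core_gh2n) < pos(config$core_gh2d) &&
      pos(config$core_gh2d) < pos(config$core_gh2c)) {
    return(list(layout = "canonical", evidence = "core:GH2N<GH2d<GH2C"))
  }
  if (has(config$core_gh2n) && !has(config$core_gh2d) && has(config$core_gh2c) &&
      pos(config$core_gh2n) < pos(config$core_gh2c) &&
      !is.na(gh2d_ref_length)) {
    n_end <- architecture$end[match(config$core_gh2n, el)]
    gap <- pos(config$core_gh2c) - n_end - 1
    win <- config$gh2d_gap_window * gh2d_ref_length
    if (gap >= win[1] && gap <= win[2]) {
      return(list(layout = "gh2d_like_gap",
                  evidence = sprintf("core:GH2d-sized gap (%d aa, window %.0f-%.0f)",
                                     gap, win[1], win[2])))
    }
  }
  list(layout = "incomplete", evidence = "core:incomplete")
}

#' Classify one architecture into a DA type
#'
#' Applies the five-way decision order to a sequence that passed
#' [filter_gh2c()] and whose core layout is not `incomplete`:
#' \enumerate{
#'   \item a small-subunit domain (Bgal_Small_N) downstream of GH2C makes
#'     DA type 3 (subtypes: `3-canonical` when DUF4981 and GH2d are both
#'     annotated, `3-appended` when decoration domains are attached,
#'     `3-replaced` when the linker or GH2d is replaced by an unannotated
#'     stretch of similar length);
#'   \item DUF4982 immediately downstream of GH2C, together with a C-terminal
#'     extension of at least `min_ct_extension` residues or further
#'     identified modules, makes DA type 5;
#'   \item an unannotated C-terminal extension of at least
#'     `min_ct_extension` residues makes DA type 4;
#'   \item otherwise the core-only call is `1or2`, pending bicistronic
#'     resolution by [resolve_bicistronic()].
#' }
#' N-terminal decoration domains (lectins, surface-anchoring signals) are
#' recorded as flags and never change the type.
#'
#' @param architecture One sequence's architecture tibble (non-empty).
#' @param config A [gh2_config()].
#' @param gh2d_ref_length Reference GH2d span for the gap rule.
#' @return One-row tibble: `seq_id`, `da_type`, `subtype`, `evidence`
#'   (`;`-joined fired rules), `flags`.
#' @export
classify_da <- function(architecture, config = gh2_config(),
                        gh2d_ref_length = config$gh2d_ref_length) {
  id <- architecture$seq_id[1]
  core <- detect_core(architecture, config, gh2d_ref_length)
  ev <- core$evidence
  el <- architecture$element
  seq_len_aa <- architecture$seq_length[1]

  first_core_start <- suppressWarnings(
    min(architecture$start[el %in% core_domains(config)]))
  nflag <- architecture |>
    filter(.data$element %in% config$decoration_domains,
           .data$end < first_core_start)
  flags <- if (nrow(nflag)) paste0("nterm:", paste(nflag$element, collapse = ","))
  else ""

  if (core$layout == "incomplete") {
    return(tibble(seq_id = id, da_type = "unassigned", subtype = "unassigned",
                  evidence = paste(c(ev, "unassignable:incomplete core"),
                                   collapse = ";"),
                  flags = flags))
  }

  gh2c_i <- match(config$core_gh2c, el)
  gh2c_end <- architecture$end[gh2c_i]
  down <- filter(architecture, .data$start > architecture$start[gh2c_i])
  last_end <- max(architecture$end)
  tail_len <- seq_len_aa - last_end
  dec_down <- intersect(down$element, config$decoration_domains)

  if (config$small_subunit_domain %in% down$element) {
    ev <- c(ev, "type3:Bgal_Small_N downstream of GH2C")
    subtype <- if (length(dec_down)) {
      ev <- c(ev, paste0("subtype:decorations ", paste(dec_down, collapse = ",")))
      "3-appended"
    } else if (config$linker_type3 %in% down$element &&
               core$layout == "canonical") {
      ev <- c(ev, "subtype:DUF4981 linker present, core canonical")
      "3-canonical"
    } else {
      ev <- c(ev, "subtype:linker and/or GH2d replaced by unannotated stretch")
      "3-replaced"
    }
    return(tibble(seq_id = id, da_type = "3", subtype = subtype,
                  evidence = paste(ev, collapse = ";"), flags = flags))
  }

  duf5_i <- match(config$linker_type5, down$element)
  if (!is.na(duf5_i)) {
    # immediately downstream: first element after GH2C
    imm <- down$element[order(down$start)][1] == config$linker_type5
    further <- setdiff(down$element, config$linker_type5)
    if (imm && (tail_len >= config$min_ct_extension || length(further))) {
      ev <- c(ev, "type5:DUF4982 immediately downstream of GH2C",
              if (tail_len >= config$min_ct_extension)
                sprintf("type5:Ct extension %d aa", tail_len)
              else sprintf("type5:further modules %s",
                           paste(further, collapse = ",")))
      return(tibble(seq_id = id, da_type = "5", subtype = "5-unassigned",
                    evidence = paste(ev, collapse = ";"), flags = flags))
    }
  }

  if (tail_len >= config$min_ct_extension) {
    ev <- c(ev, sprintf("type4:unannotated Ct extension %d aa", tail_len))
    return(tibble(seq_id = id, da_type = "4", subtype = "4",
                  evidence = paste(ev, collapse = ";"), flags = flags))
  }

  ev <- c(ev, sprintf("core-only:Ct tail %d aa below %d-residue floor",
                      tail_len, config$min_ct_extension))
  tibble(seq_id = id, da_type = "1or2", subtype = "1or2",
         evidence = paste(ev, collapse = ";"), flags = flags)
}

#' Resolve core-only calls into monocistronic / bicistronic types
#'
#' DA types 1 and 2 share the same single-gene architecture; a `1or2` call
#' becomes type 2 only with external evidence: either a standalone
#' small-subunit (LacM) partner locus recorded in the companion table, or
#' membership of a GH2C subcluster tagged as bicistronic. Without evidence
#' the call defaults to type 1.
#'
#' @param calls Classification tibble containing `1or2` rows.
#' @param companion Optional tibble with column `seq_id` plus `partner`
#'   (LacM record id or `NA`) and/or `subcluster`.
#' @param bicistronic_subclusters Character vector of subcluster ids tagged
#'   bicistronic.
#' @param known_ids Optional universe of record ids; a partner id outside it
#'   warns and defaults the call to type 1.
#' @return `calls` with `1or2` rows resolved to `"1"` or `"2"`.
#' @export
resolve_bicistronic <- function(calls, companion = NULL,
                                bicistronic_subclusters = character(),
                                known_ids = NULL) {
  pending <- calls$da_type == "1or2"
  if (!any(pending)) return(calls)
  for (i in which(pending)) {
    id <- calls$seq_id[i]
    partner <- NA_character_
    sub <- NA_character_
    if (!is.null(companion) && id %in% companion$seq_id) {
      row <- companion[match(id, companion$seq_id), ]
      if ("partner" %in% names(row)) partner <- row$partner
      if ("subcluster" %in% names(row)) sub <- as.character(row$subcluster)
    }
    if (!is.na(partner) && !is.null(known_ids) && !partner %in% known_ids) {
      warn(paste0("companion id not found: ", partner, " (for ", id,
                  "); defaulting to DA type 1"))
      partner <- NA_character_
    }
    if (!is.na(partner)) {
      calls$da_type[i] <- "2"
      calls$subtype[i] <- "2"
      calls$evidence[i] <- paste0(calls$evidence[i],
                                  ";type2:LacM partner ", partner)
    } else if (!is.na(sub) && sub %in% bicistronic_subclusters) {
      calls$da_type[i] <- "2"
      calls$subtype[i] <- "2"
      calls$evidence[i] <- paste0(calls$evidence[i],
                                  ";type2:bicistronic subcluster ", sub)
    } else {
      calls$da_type[i] <- "1"
      calls$subtype[i] <- "1"
      calls$evidence[i] <- paste0(calls$evidence[i],
                                  ";type1:no bicistronic evidence")
    }
  }
  calls
}

#' End-to-end DA classification of an annotation set
#'
#' Runs the selection filter, architecture building, core detection, the
#' five-way classifier and bicistronic resolution over a whole dataset. The
#' reference GH2d length for the gap rule is the dataset median GH2d span
#' unless fixed in the config.
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @param hits Domain-hit tibble.
#' @param config A [gh2_config()].
#' @param companion Optional companion-locus table (see
#'   [resolve_bicistronic()]).
#' @param bicistronic_subclusters Subcluster ids treated as bicistronic.
#' @return Object of class `gh2_calls`: tibble with one row per sequence
#'   (`seq_id`, `da_type`, `subtype`, `evidence`, `flags`); sequences
#'   rejected by the filter have `da_type = "rejected"` and the reason as
#'   subtype. The architectures used are attached as attribute
#'   `"architectures"`.
#' @export
gh2_classify <- function(seqs, hits, config = gh2_config(), companion = NULL,
                         bicistronic_subclusters = character()) {
  flt <- filter_gh2c(hits, config)
  arch <- build_architectures(filter(hits, .data$seq_id %in%
                                       flt$seq_id[flt$pass]),
                              seqs, config)
  ref_len <- config$gh2d_ref_length
  if (is.na(ref_len)) {
    spans <- arch |> filter(.data$element == config$core_gh2d)
    ref_len <- if (nrow(spans)) median(spans$end - spans$start + 1) else NA_real_
  }
  calls <- arch |>
    dplyr::group_split(.data$seq_id) |>
    purrr::map(classify_da, config = config, gh2d_ref_length = ref_len) |>
    bind_rows()
  calls <- resolve_bicistronic(calls, companion, bicistronic_subclusters,
                               known_ids = seqs$id)
  rejected <- flt |>
    filter(!.data$pass) |>
    mutate(da_type = "rejected", subtype = .data$reason,
           evidence = paste0("filter:", .data$reason), flags = "") |>
    select("seq_id", "da_type", "subtype", "evidence", "flags")
  # passing sequences with empty architectures cannot occur (they have GH2C)
  out <- bind_rows(calls, rejected) |> arrange(.data$seq_id)
  structure(out, class = c("gh2_calls", class(out)),
            architectures = arch, gh2d_ref_length = ref_len)
}

#' Tally sequences per DA type
#'
#' Deterministic per-type counts from a per-sequence classification table in
#' the package's report format (or any tibble carrying a `da_type` column).
#'
#' @param calls Classification tibble.
#' @param drop_rejected Drop filter-rejected rows before counting.
#' @return Tibble with columns `da_type`, `n`, sorted by `da_type`.
#' @export
tally_da_types <- function(calls, drop_rejected = TRUE) {
  x <- tibble(seq_id = calls$seq_id, da_type = calls$da_type)
  if (drop_rejected) x <- filter(x, .data$da_type != "rejected")
  x |> count(.data$da_type) |> arrange(.data$da_type)
}

#' Write / read the classification report
#'
#' Tab-separated with columns `seq_id`, `da_type`, `subtype`, `evidence`,
#' `flags` (the per-sequence layout used by the deposited DA tables).
#'
#' @param calls Classification tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_da_report <- function(calls, path) {
  readr::write_tsv(as_tibble(calls)[, c("seq_id", "da_type", "subtype",
                                        "evidence", "flags")], path)
  invisible(path)
}

#' @rdname write_da_report
#' @export
read_da_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Audit classification misses against generator truth
#'
#' Explains each disagreement between called and true DA types by the
#' annotation corruption that caused it: the audit lists, per miss, the
#' domain hits present in the uncorrupted truth annotations but absent from
#' the observed table, and marks the miss explained when a dropped hit is a
#' signature domain (core, linker or small-subunit).
#'
#' @param calls `gh2_calls` from [gh2_classify()] on the noisy table.
#' @param truth Truth tibble with `seq_id`, `da_type`.
#' @param hits Observed (noisy) domain table.
#' @param truth_hits Uncorrupted domain table.
#' @param config A [gh2_config()].
#' @return Tibble of misses: `seq_id`, `true_type`, `called_type`,
#'   `dropped_domains`, `explained`.
#' @export
audit_classification <- function(calls, truth, hits, truth_hits,
                                 config = gh2_config()) {
  cmp <- as_tibble(calls) |>
    select("seq_id", called_type = "da_type") |>
    dplyr::inner_join(truth |> select("seq_id", true_type = "da_type"),
                      by = "seq_id") |>
    filter(.data$called_type != "rejected",
           .data$called_type != .data$true_type)
  dropped <- dplyr::anti_join(
    truth_hits |> select("seq_id", "domain", "env_start"),
    hits |> select("seq_id", "domain", "env_start"),
    by = c("seq_id", "domain", "env_start"))
  cmp |>
    dplyr::rowwise() |>
    mutate(
      dropped_domains = paste(dropped$domain[dropped$seq_id == .data$seq_id],
                              collapse = ","),
      explained = any(dropped$domain[dropped$seq_id == .data$seq_id] %in%
                        signature_domains(config))
    ) |>
    ungroup()
}
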
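#' Map a reference residue to its alignment column
#'
#' Counts non-gap positions of the reference row until the anchor's ungapped
#' position is reached. The residue found at the mapped column must equal
#' the anchor's expected residue; a mismatch is a hard error guarding
#' against off-by-one anchor definitions.
#'
#' @param msa A `gh2_msa` containing the reference row.
#' @param ref_id Reference sequence id.
#' @param position 1-based ungapped residue index in the reference.
#' @param expected_residue Single letter expected at that position.
#' @return Integer column index.
#' @export
anchor_to_column <- function(msa, ref_id, position, expected_residue) {
  row <- msa$aligned[match(ref_id, msa$id)]
  if (is.na(row)) abort(paste0("reference id not in MSA: ", ref_id))
  cc <- chars(row)
  resi <- cumsum(cc != "-")
  col <- match(position, resi)
  if (is.na(col)) {
    abort(sprintf("anchor position %d beyond reference length %d",
                  position, max(resi)))
  }
  if (cc[col] != expected_residue) {
    abort(sprintf(
      "anchor mismatch: expected %s at %s position %d but reference holds %s",
      expected_residue, ref_id, position, cc[col]))
  }
  col
}

#' Conservation of one alignment column
#'
#' Percentage of rows carrying the target residue: the reference row's
#' residue (`mode = "to_reference"`) or the modal residue of the column
#' (`mode = "modal"`, the default — identity to the column consensus). Gaps
#' never count as matches; by default they stay in the denominator
#' (`count_gaps = TRUE`). Banding follows the strict >50% reading: 100%
#' maps to `"100"`, anything above 50% to `">=50"`, the rest (50% included)
#' to `"<50"`.
#'
#' @param msa A `gh2_msa`.
#' @param column Column index.
#' @param mode `"modal"` or `"to_reference"`.
#' @param ref_id Reference id (required for `to_reference`).
#' @param count_gaps Keep gap rows in the denominator.
#' @param rows Optional subset of sequence ids to profile.
#' @return List with `percent` (0-100), `band`, `target` residue, and
#'   `freq` (named residue counts).
#' @export
column_conservation <- function(msa, column, mode = c("modal", "to_reference"),
                                ref_id = NULL, count_gaps = TRUE,
                                rows = NULL) {
  mode <- match.arg(mode)
  stopifnot(column >= 1, column <= attr(msa, "n_columns"))
  ids <- rows %||% msa$id
  col <- substr(msa$aligned[match(ids, msa$id)], column, column)
  freq <- table(col)
  target <- if (mode == "to_reference") {
    if (is.null(ref_id)) abort("to_reference mode requires ref_id")
    substr(msa$aligned[match(ref_id, msa$id)], column, column)
  } else {
    resid <- col[col != "-"]
    if (!length(resid)) return(list(percent = 0, band = "<50",
                                    target = NA_character_, freq = freq))
    tt <- table(resid)
    # deterministic modal residue: highest count, alphabetic tie-break
    names(tt)[order(-tt, names(tt))][1]
  }
  denom <- if (count_gaps) length(col) else sum(col != "-")
  matches <- sum(col == target & col != "-")
  percent <- if (denom == 0) 0 else 100 * matches / denom
  list(percent = percent, band = conservation_band(matches, denom),
       target = target, freq = freq)
}

# band from exact counts so boundaries are not floating-point sensitive
conservation_band <- function(matches, denom) {
  if (denom > 0 && matches == denom) "100"
  else if (denom > 0 && 2 * matches > denom) ">=50"
  else "<50"
}

#' Conservation band of a percentage
#'
#' Pure banding function: 100 maps to `"100"`, values strictly above 50 to
#' `">=50"`, everything else (50 included) to `"<50"`.
#'
#' @param percent Numeric vector in `[0, 100]`.
#' @return Character vector of bands.
#' @export
band_of_percent <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  dplyr::case_when(percent == 100 ~ "100",
                   percent > 50 ~ ">=50",
                   TRUE ~ "<50")
}

#' Profile active-site anchors across an alignment
#'
#' Maps each anchor through the reference row, measures column conservation
#' over all rows and, when a subset is supplied (e.g. the BIG1-tagged
#' sequences), within the subset and within the rest separately. Two anchors
#' mapping to the same column are both reported with a warning.
#'
#' @param msa A `gh2_msa`.
#' @param anchors Tibble with columns `ref_id`, `position`,
#'   `expected_residue`, `role`.
#' @param subset Optional character vector of sequence ids.
#' @param mode Conservation mode, see [column_conservation()].
#' @param count_gaps See [column_conservation()].
#' @return A `gh2_conservation` tibble: `ref_id`, `position`, `role`,
#'   `column`, `percent`, `band`, `subset_percent`, `rest_percent` (the
#'   last two `NA` without a subset).
#' @export
profile_anchors <- function(msa, anchors, subset = NULL,
                            mode = c("modal", "to_reference"),
                            count_gaps = TRUE) {
  mode <- match.arg(mode)
  out <- purrr::pmap(anchors[, c("ref_id", "position", "expected_residue",
                                 "role")],
                     function(ref_id, position, expected_residue, role) {
    col <- anchor_to_column(msa, ref_id, position, expected_residue)
    full <- column_conservation(msa, col, mode, ref_id, count_gaps)
    subset_percent <- NA_real_
    rest_percent <- NA_real_
    if (!is.null(subset) && length(subset)) {
      subset_percent <- column_conservation(msa, col, mode, ref_id,
                                            count_gaps,
                                            rows = intersect(msa$id, subset)
                                            )$percent
      rest <- setdiff(msa$id, subset)
      if (length(rest)) {
        rest_percent <- column_conservation(msa, col, mode, ref_id,
                                            count_gaps, rows = rest)$percent
      }
    }
    tibble(ref_id = ref_id, position = position, role = role, column = col,
           percent = full$percent, band = full$band,
           subset_percent = subset_percent, rest_percent = rest_percent)
  }) |> bind_rows()
  if (anyDuplicated(out$column)) {
    warn(paste0("anchors map to shared column(s): ",
                paste(unique(out$column[duplicated(out$column)]),
                      collapse = ", ")))
  }
  structure(out, class = c("gh2_conservation", class(tibble())))
}

#' Documented active-site anchor presets
#'
#' Catalytic-pocket positions of two well characterised GH2
#' beta-galactosidases, usable once the corresponding reference sequence is
#' present in the alignment: the Bacillus circulans enzyme (acid/base Glu
#' 447, nucleophile Glu 532, Tyr 511, and acceptor-site residues Lys 409,
#' Tyr 449, Asp 481, Trp 570) and the Thermotoga maritima enzyme's acceptor
#' platform Trp 959. These are presets, not hard-coded behaviour: pass the
#' returned tibble (or your own) to [profile_anchors()].
#'
#' @param ref_id Id of the reference row in your alignment.
#' @param set `"bcirculans"` or `"tmaritima"`.
#' @return Anchor tibble (`ref_id`, `position`, `expected_residue`, `role`).
#' @export
gh2_default_anchors <- function(ref_id, set = c("bcirculans", "tmaritima")) {
  set <- match.arg(set)
  if (set == "bcirculans") {
    tibble(ref_id = ref_id,
           position = c(409L, 447L, 449L, 481L, 511L, 532L, 570L),
           expected_residue = c("K", "E", "Y", "D", "Y", "E", "W"),
           role = c("acceptor site", "acid/base", "acceptor site",
                    "acceptor site", "catalytic triad", "nucleophile",
                    "acceptor site"))
  } else {
    tibble(ref_id = ref_id, position = 959L, expected_residue = "W",
           role = "acceptor platform")
  }
}
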
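#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into a tibble of sequence records. Identifiers are the
#' first whitespace-delimited token of each header; the remainder is kept as
#' the description. Residues must be the 20 canonical amino acids or X
#' (uppercase, no gaps); violations are reported with the line numbers of the
#' offending record.
#'
#' @param path FASTA file.
#' @return Tibble with columns `id`, `residues`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, ">"))) {
    abort(paste0("empty or headerless FASTA: ", path))
  }
  # validate residue lines on the raw text so offending line numbers can be
  # reported (the parser below silently drops unknown letters)
  is_body <- !startsWith(lines, ">") & nzchar(trimws(lines))
  bad_lines <- which(is_body &
                       grepl(paste0("[^", paste(gh2_alphabet(),
                                                collapse = ""), "]"),
                             toupper(trimws(lines))))
  if (length(bad_lines)) {
    abort(paste0("invalid residues at line ",
                 paste(bad_lines, collapse = ", "),
                 "; allowed letters are the 20 amino acids and X"))
  }
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) abort(paste0("empty FASTA: ", path))
  hdr <- names(set)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  header_lines <- which(startsWith(lines, ">"))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    at <- header_lines[sub("\\s.*$", "", sub("^>", "", lines[header_lines])) %in% dup]
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
                 " (header line ", paste(at, collapse = ", "), ")"))
  }
  res <- toupper(as.character(set))
  bad <- which(!residues_ok(res) | nchar(res) < 1)
  if (length(bad)) {
    abort(paste0(
      "invalid residues in record(s): ",
      paste(sprintf("%s (starting line %d)", ids[bad], header_lines[bad]),
            collapse = ", "),
      "; allowed letters are the 20 amino acids and X"))
  }
  tibble(id = ids, residues = unname(res), description = desc)
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with `id`, `residues` and optionally `description`.
#' @param path Output file.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  hdr <- ifelse(nchar(desc) > 0, paste(seqs$id, desc), seqs$id)
  out <- purrr::map2(hdr, seqs$residues, function(h, r) {
    body <- substring(r, seq(1, nchar(r), width),
                      pmin(seq(1, nchar(r), width) + width - 1, nchar(r)))
    c(paste0(">", h), body)
  })
  writeLines(unlist(out), path)
  invisible(path)
}

#' Read per-sequence domain annotations
#'
#' Two dialects are supported. `tsv` expects columns `seq_id`, `domain`,
#' `env_start`, `env_end`, `model_coverage` (a header row is required).
#' `domtblout` parses HMMER3 `hmmscan --domtblout` records, taking the
#' envelope from/to columns as coordinates and computing the fraction of the
#' profile matched as `(hmm_to - hmm_from + 1) / model_length`.
#'
#' Coordinates are 1-based inclusive Pfam envelope coordinates everywhere in
#' the package; they are validated on load.
#'
#' @param path Annotation file.
#' @param dialect `"tsv"` or `"domtblout"`.
#' @return Tibble of domain hits with a `source` column naming the dialect.
#' @export
read_domain_table <- function(path, dialect = c("tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("domain table not found: ", path))
  hits <- if (dialect == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      seq_id = readr::col_character(),
      domain = readr::col_character(),
      env_start = readr::col_integer(),
      env_end = readr::col_integer(),
      model_coverage = readr::col_double()
    ))
    mutate(tab, source = "tsv")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    if (!length(lines)) abort(paste0("no records in domtblout: ", path))
    fields <- strsplit(trimws(lines), "\\s+")
    short <- which(lengths(fields) < 21)
    if (length(short)) {
      abort(paste0("malformed domtblout record(s) at line ",
                   paste(short, collapse = ", ")))
    }
    tibble(
      seq_id = vapply(fields, `[`, "", 4),
      domain = vapply(fields, `[`, "", 1),
      env_start = as.integer(vapply(fields, `[`, "", 20)),
      env_end = as.integer(vapply(fields, `[`, "", 21)),
      model_coverage =
        (as.numeric(vapply(fields, `[`, "", 17)) -
           as.numeric(vapply(fields, `[`, "", 16)) + 1) /
        as.numeric(vapply(fields, `[`, "", 3)),
      source = "domtblout"
    )
  }
  validate_hits(hits)
  hits
}

#' Validate domain-hit invariants
#'
#' Checks 1-based inclusive coordinates (`1 <= env_start <= env_end`), model
#' coverage in `[0, 1]`, and — when sequences are supplied — that every hit
#' resolves to a known sequence and lies within its length.
#'
#' @param hits Domain-hit tibble.
#' @param seqs Optional sequence tibble (from [read_fasta()]).
#' @return `hits`, invisibly.
#' @export
validate_hits <- function(hits, seqs = NULL) {
  bad <- which(hits$env_start < 1 | hits$env_start > hits$env_end)
  if (length(bad)) {
    abort(paste0("invalid envelope coordinates (1-based, start <= end) in row ",
                 paste(bad, collapse = ", ")))
  }
  bad <- which(hits$model_coverage < 0 | hits$model_coverage > 1)
  if (length(bad)) {
    abort(paste0("model_coverage outside [0, 1] in row ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(seqs)) {
    unknown <- setdiff(unique(hits$seq_id), seqs$id)
    if (length(unknown)) {
      abort(paste0("hits reference unknown sequence(s): ",
                   paste(unknown, collapse = ", ")))
    }
    len <- setNames(nchar(seqs$residues), seqs$id)
    over <- which(hits$env_end > len[hits$seq_id])
    if (length(over)) {
      abort(paste0("envelope end beyond sequence length in row ",
                   paste(over, collapse = ", ")))
    }
  }
  invisible(hits)
}

#' Write a domain-hit table (tsv dialect)
#'
#' @param hits Domain-hit tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(hits, path) {
  readr::write_tsv(hits[, c("seq_id", "domain", "env_start", "env_end",
                            "model_coverage")], path)
  invisible(path)
}
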
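#' Aggregate a run report
#'
#' Counts per DA type and subtype, filter rejections by reason, and — when a
#' labeled tree is supplied — the DA-vs-tree concordance summary.
#'
#' @param calls A `gh2_calls` tibble.
#' @param tree Optional `gh2_tree` over classified sequences.
#' @return A `gh2_report` list: `type_counts`, `subtype_counts`,
#'   `rejections`, and optionally `concordance`.
#' @export
gh2_report <- function(calls, tree = NULL) {
  calls <- as_tibble(calls)
  out <- list(
    type_counts = tally_da_types(calls),
    subtype_counts = calls |>
      filter(.data$da_type != "rejected") |>
      count(.data$da_type, .data$subtype) |>
      arrange(.data$da_type, .data$subtype),
    rejections = calls |>
      filter(.data$da_type == "rejected") |>
      count(reason = .data$subtype) |>
      arrange(.data$reason)
  )
  if (!is.null(tree)) {
    labels <- calls |>
      filter(.data$seq_id %in% tree$phylo$tip.label) |>
      select("seq_id", label = "da_type")
    out$concordance <- concordance(tree, labels)
  }
  structure(out, class = "gh2_report")
}

#' @export
print.gh2_report <- function(x, ...) {
  cat("<gh2_report>\nDA type counts:\n")
  print(x$type_counts)
  if (nrow(x$rejections)) {
    cat("Filter rejections:\n")
    print(x$rejections)
  }
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Structured stage log line
#'
#' One-line, greppable log record: stage, named counts, seed.
#' @param stage Stage name.
#' @param ... Named scalar fields.
#' @param verbose Emit via [message()] (default) or return only.
#' @return The formatted line, invisibly.
#' @export
gh2_log <- function(stage, ..., verbose = TRUE) {
  fields <- list(...)
  line <- paste0("[gh2arch] stage=", stage,
                 if (length(fields))
                   paste0(" ", paste(names(fields), unlist(fields),
                                     sep = "=", collapse = " ")) else "")
  if (verbose) message(line)
  invisible(line)
}
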
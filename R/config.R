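#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one flat list so a whole
#' run is reproducible from a single object (or YAML file). Defaults follow
#' the published GH2 analysis protocol: a sequence enters the study only if it
#' carries a single catalytic GH2C domain covering at least 70% of the Pfam
#' model; an unannotated C-terminal stretch counts as an extension from 60
#' residues; a module is tagged BIG1 when identity to a BIG1 reference
#' exceeds 40% with reference coverage above 60% (both strict); trees use
#' 100 bootstrap replicates condensed below 50% support.
#'
#' @param ... named overrides of any default field (unknown names error).
#' @return A list of class `gh2_config`.
#' @examples
#' cfg <- gh2_config(min_gh2c_coverage = 0.8)
#' cfg$min_gh2c_coverage
#' @export
gh2_config <- function(...) {
  cfg <- list(
    # selection filter
    min_gh2c_coverage = 0.70,
    catalytic_blacklist = c("PKinase", "Glyco_transf_2", "Lipase_GDSL",
                            "Polysacc_deac_1", "Glyco_hydro_20"),
    # core layout
    core_gh2n = "GH2N",
    core_gh2d = "GH2d",
    core_gh2c = "GH2C",
    gh2d_gap_window = c(0.7, 1.3),
    gh2d_ref_length = NA_real_,  # NA: use the median GH2d span in the dataset
    # classifier vocabulary
    linker_type3 = "DUF4981",
    linker_type5 = "DUF4982",
    small_subunit_domain = "Bgal_Small_N",
    decoration_domains = c("RicinB_lectin_2", "YSIRK_signal", "Laminin_G_3",
                           "NPCBM", "F5_F8_type_C"),
    # C-terminal extensions
    min_ct_extension = 60,
    big1_min_identity = 0.40,
    big1_min_coverage = 0.60,
    ct_id_threshold = 0.30,
    ct_length_bands = list(c(60, 300), c(301, 1100)),
    # architecture building
    overlap_fraction = 0.5,
    # alignment / phylogeny
    gap_open = -11,
    gap_extend = -1,
    distance_method = "kimura",
    deletion = "pairwise",
    n_replicates = 100,
    condense_threshold = 0.5
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      abort(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    }
    cfg <- modifyList(cfg, dots)
  }
  validate_config(cfg)
  structure(cfg, class = "gh2_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_gh2c_coverage > 0, cfg$min_gh2c_coverage <= 1,
    cfg$min_ct_extension >= 0,
    length(cfg$gh2d_gap_window) == 2,
    cfg$gh2d_gap_window[1] <= cfg$gh2d_gap_window[2],
    cfg$big1_min_identity > 0, cfg$big1_min_identity < 1,
    cfg$big1_min_coverage > 0, cfg$big1_min_coverage < 1,
    cfg$gap_open <= cfg$gap_extend, cfg$gap_extend < 0,
    cfg$n_replicates >= 1,
    cfg$condense_threshold >= 0, cfg$condense_threshold <= 1
  )
  invisible(cfg)
}

#' Read a configuration file
#'
#' Loads a flat-key YAML file and merges it over [gh2_config()] defaults.
#'
#' @param path YAML file with a subset of config keys.
#' @return A `gh2_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$ct_length_bands)) {
    vals$ct_length_bands <- lapply(vals$ct_length_bands, as.numeric)
  }
  do.call(gh2_config, vals %||% list())
}

#' @export
print.gh2_config <- function(x, ...) {
  cat("<gh2_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.list(val)) val <- paste(vapply(val, paste, "", collapse = "-"),
                                   collapse = ", ")
    cat(sprintf("  %-22s %s\n", nm, paste(val, collapse = " ")))
  }
  invisible(x)
}

core_domains <- function(cfg) c(cfg$core_gh2n, cfg$core_gh2d, cfg$core_gh2c)

# Signature domains whose loss changes a DA-type verdict; used by the
# classification audit.
signature_domains <- function(cfg) {
  c(core_domains(cfg), cfg$linker_type3, cfg$linker_type5,
    cfg$small_subunit_domain)
}
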
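#' Configuration of the synthetic GH2 dataset generator
#'
#' The generator emits a dataset with the statistical structure the analysis
#' assumes: a random bifurcating phylogeny; one ancestral sequence per
#' protein module evolving along it under an independent-site substitution
#' process; domain-architecture types painted onto clades following the
#' domain-gain evolutionary scenario (the root state is the three-domain
#' core; designated clades gain a small-subunit module, a DUF4982 linker
#' plus extension, or an unannotated extension; one subclade of the
#' canonical clade is emitted as two loci to mimic bicistronic enzymes);
#' planted invariant alignment columns inside a designated clade; and
#' annotation noise (hit dropout, coverage jitter, hybrid and
#' duplicated-GH2C contaminants) applied only after the ground truth is
#' recorded.
#'
#' @param n_taxa Number of leaves (default 60).
#' @param branch_mean Mean of the exponential branch lengths (substitution
#'   time units; default 0.3).
#' @param rate Substitutions per site along a unit branch (default 0.1).
#' @param module_lengths Named lengths of the simulated modules.
#' @param frac_type3,frac_type5,frac_type4 Target clade sizes as fractions
#'   of `n_taxa`.
#' @param frac_type2 Target bicistronic subclade size as a fraction of the
#'   canonical clade.
#' @param planted_positions GH2C positions held invariant within the
#'   designated clade (the type-5-like clade), mimicking conserved
#'   active-site residues.
#' @param base_coverage Model coverage written for uncorrupted hits.
#' @param dropout Per-hit removal probability.
#' @param jitter Half-width of uniform coverage perturbation.
#' @param hybrid_count Sequences receiving an extra blacklist-domain hit.
#' @param duplicate_gh2c_count Sequences receiving a second GH2C hit.
#' @param seed Integer seed (mandatory).
#' @return A `gh2_synth_config` list.
#' @export
synth_config <- function(n_taxa = 60, branch_mean = 0.3, rate = 0.1,
                         module_lengths = c(GH2N = 180, GH2d = 300,
                                            GH2C = 320, DUF4981 = 100,
                                            DUF4982 = 90, Bgal_Small_N = 220,
                                            BIG1 = 100, EXT4 = 200,
                                            TAIL5 = 130),
                         frac_type3 = 0.35, frac_type2 = 0.30,
                         frac_type5 = 0.15, frac_type4 = 0.12,
                         planted_positions = c(40L, 80L, 120L, 160L, 200L,
                                               240L, 280L),
                         base_coverage = 0.95, dropout = 0, jitter = 0,
                         hybrid_count = 0, duplicate_gh2c_count = 0, seed) {
  if (missing(seed)) abort("synth_config() requires an explicit seed")
  stopifnot(n_taxa >= 3, branch_mean > 0, rate >= 0,
            dropout >= 0, dropout <= 1, jitter >= 0, jitter <= 1,
            all(planted_positions >= 1),
            all(planted_positions <= module_lengths[["GH2C"]]))
  structure(list(n_taxa = n_taxa, branch_mean = branch_mean, rate = rate,
                 module_lengths = module_lengths, frac_type3 = frac_type3,
                 frac_type2 = frac_type2, frac_type5 = frac_type5,
                 frac_type4 = frac_type4,
                 planted_positions = as.integer(planted_positions),
                 base_coverage = base_coverage, dropout = dropout,
                 jitter = jitter, hybrid_count = hybrid_count,
                 duplicate_gh2c_count = duplicate_gh2c_count,
                 seed = as.integer(seed)),
            class = "gh2_synth_config")
}

#' Sample a random bifurcating tree
#'
#' Uniform random topology with exponential branch lengths; deterministic
#' for a given seed.
#'
#' @param n_taxa Number of leaves (at least 3).
#' @param seed Integer seed.
#' @param branch_mean Mean branch length.
#' @return A `gh2_tree` (rooted, bifurcating, tips `t01`, `t02`, ...).
#' @export
sample_tree <- function(n_taxa, seed, branch_mean = 0.3) {
  stopifnot(n_taxa >= 3)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  phy <- ape::rtree(n_taxa, br = function(m) rexp(m, 1 / branch_mean))
  phy$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  new_gh2_tree(phy, meta = list(seed = seed, branch_mean = branch_mean))
}

#' Evolve sequences along a tree
#'
#' Independent-site substitution: along a branch of length `t`, each site
#' changes with probability `1 - exp(-rate * t)`, replaced uniformly by one
#' of the other 19 amino acids. Sites listed in `planted` are exempted
#' within the clade under `clade_node` (the state frozen at that clade's
#' root). Rate 0 returns the root sequence at every leaf.
#'
#' @param tree A `gh2_tree` (rooted).
#' @param root_seq Ancestral residue string.
#' @param rate Substitutions per site per unit branch.
#' @param planted Integer positions exempt from substitution in-clade.
#' @param clade_node Internal node number of the protected clade (`NA`:
#'   none).
#' @return Named character vector of leaf sequences.
#' @export
evolve_sequences <- function(tree, root_seq, rate, planted = integer(),
                             clade_node = NA_integer_) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  aa <- gh2_alphabet()[1:20]
  seqs <- vector("list", ntip + phy$Nnode)
  out <- setNames(character(ntip), phy$tip.label)
  walk <- function(node, seq, in_clade) {
    kids <- which(phy$edge[, 1] == node)
    for (k in kids) {
      child <- phy$edge[k, 2]
      len <- phy$edge.length[k]
      child_in <- in_clade || (!is.na(clade_node) && child == clade_node)
      p <- 1 - exp(-rate * len)
      s <- seq
      if (p > 0) {
        hit <- which(runif(length(s)) < p)
        if (child_in && length(planted)) hit <- setdiff(hit, planted)
        for (i in hit) {
          s[i] <- sample(setdiff(aa, s[i]), 1)
        }
      }
      if (child <= ntip) out[phy$tip.label[child]] <<- paste(s, collapse = "")
      else walk(child, s, child_in)
    }
  }
  walk(root, chars(root_seq), FALSE)
  out
}

# deterministic clade choice: prefer nodes whose size sits in a band around
# the target and whose stem edge is longest (well-separated lineages, as a
# domain-gain scenario presumes); fall back to the disjoint node closest in
# size
pick_clade <- function(phy, target_size, excluded_leaves = character()) {
  ntip <- length(phy$tip.label)
  sets <- clade_sets(phy)
  nodes <- seq_along(sets) + ntip
  ok <- vapply(sets, function(s) !any(s %in% excluded_leaves) &&
                 length(s) < ntip - length(excluded_leaves), TRUE)
  ok[1] <- FALSE  # never the root
  if (!any(ok)) abort("no clade available for scenario painting")
  stem <- vapply(nodes, function(nd) {
    k <- which(phy$edge[, 2] == nd)
    if (length(k)) phy$edge.length[k] else 0
  }, 1)
  size <- lengths(sets)
  band <- ok & size >= max(2, floor(0.6 * target_size)) &
    size <= ceiling(1.5 * target_size)
  cand <- if (any(band)) which(band) else which(ok)
  best <- cand[order(-(if (any(band)) stem[cand] else
    -abs(size[cand] - target_size)), cand)][1]
  list(node = nodes[best], leaves = sets[[best]])
}

#' Paint the domain-architecture scenario onto a tree
#'
#' Assigns every leaf a DA type following the domain-gain model: the root
#' state is the core-only architecture (type 1); one well-separated clade
#' gains the small-subunit module (type 3); within it one subclade is split
#' into two loci (type 2, bicistronic); disjoint clades gain the DUF4982
#' linker plus extension (type 5) or a bare unannotated extension (type 4).
#'
#' @param tree A `gh2_tree`.
#' @param config A [synth_config()].
#' @return List: `types` (named per-leaf type), `nodes` (named internal node
#'   numbers for the type3/type5/type2 clades).
#' @export
paint_da_scenario <- function(tree, config) {
  phy <- tree$phylo
  n <- length(phy$tip.label)
  c3 <- pick_clade(phy, round(config$frac_type3 * n))
  c5 <- pick_clade(phy, round(config$frac_type5 * n), excluded_leaves = c3$leaves)
  c4 <- pick_clade(phy, round(config$frac_type4 * n),
                   excluded_leaves = c(c3$leaves, c5$leaves))
  # bicistronic subclade strictly inside the canonical clade: its stem must
  # hang below a strict descendant of the canonical MRCA, so bicistronic
  # leaves emerge from within the canonical radiation rather than as its
  # basal sister
  sets <- clade_sets(phy)
  ntip <- n
  parent_of <- function(nd) phy$edge[phy$edge[, 2] == nd, 1]
  inside <- which(vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    all(s %in% c3$leaves) && length(s) < length(c3$leaves) &&
      !identical(parent_of(i + ntip), c3$node)
  }, TRUE))
  if (!length(inside)) {
    inside <- which(vapply(sets, function(s) {
      all(s %in% c3$leaves) && length(s) < length(c3$leaves)
    }, TRUE))
  }
  target2 <- max(1, round(config$frac_type2 * length(c3$leaves)))
  if (length(inside)) {
    stem <- vapply(inside + ntip, function(nd) {
      k <- which(phy$edge[, 2] == nd)
      if (length(k)) phy$edge.length[k] else 0
    }, 1)
    band <- abs(lengths(sets[inside]) - target2) <=
      pmax(1, 0.5 * target2)
    cand <- if (any(band)) inside[band] else inside
    best <- cand[order(-stem[match(cand, inside)], cand)][1]
    c2 <- list(node = best + ntip, leaves = sets[[best]])
  } else {
    # canonical clade is a cherry: take the leaf hanging deepest inside it
    deep <- c3$leaves[vapply(c3$leaves, function(lf) {
      !identical(parent_of(match(lf, phy$tip.label)), c3$node)
    }, TRUE)]
    pick <- if (length(deep)) sort(deep)[1] else sort(c3$leaves)[1]
    c2 <- list(node = NA_integer_, leaves = pick)
  }
  types <- setNames(rep("1", n), phy$tip.label)
  types[c3$leaves] <- "3"
  types[c5$leaves] <- "5"
  types[c4$leaves] <- "4"
  types[c2$leaves] <- "2"
  list(types = types,
       nodes = c(type3 = c3$node, type5 = c5$node, type4 = c4$node,
                 type2 = c2$node))
}

#' Simulate a complete synthetic GH2 dataset
#'
#' Runs the whole generative scenario of [synth_config()] and returns the
#' emitted records together with the ground truth (recorded before any
#' annotation noise, so every corruption is auditable).
#'
#' @param config A [synth_config()].
#' @return A `gh2_sim` list: `sequences`, `hits` (noisy), `truth_hits`
#'   (uncorrupted), `truth` (per-record type/subtype/partner), `partners`,
#'   `tree` (true tree with GH2C-record tip labels), `big1_ref`, `planted`
#'   (positions + in-clade record ids), `scenario`, `config`.
#' @export
simulate_gh2 <- function(config) {
  stopifnot(inherits(config, "gh2_synth_config"))
  tree <- sample_tree(config$n_taxa, config$seed, config$branch_mean)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed + 1L)
  scenario <- paint_da_scenario(tree, config)
  aa <- gh2_alphabet()[1:20]
  ml <- config$module_lengths
  roots <- lapply(ml, function(L) paste(sample(aa, L, replace = TRUE),
                                        collapse = ""))
  leafseq <- lapply(names(ml), function(m) {
    evolve_sequences(tree, roots[[m]], config$rate,
                     planted = if (m == "GH2C") config$planted_positions
                     else integer(),
                     clade_node = if (m == "GH2C")
                       unname(scenario$nodes["type5"]) else NA_integer_)
  })
  names(leafseq) <- names(ml)

  modules_of <- function(type) switch(type,
    "1" = c("GH2N", "GH2d", "GH2C"),
    "2" = c("GH2N", "GH2d", "GH2C"),            # LacL locus
    "3" = c("GH2N", "GH2d", "GH2C", "DUF4981", "Bgal_Small_N"),
    "4" = c("GH2N", "GH2d", "GH2C", "EXT4"),
    "5" = c("GH2N", "GH2d", "GH2C", "DUF4982", "BIG1", "TAIL5"))
  annotated <- c("GH2N", "GH2d", "GH2C", "DUF4981", "DUF4982", "Bgal_Small_N")

  seq_rows <- list(); hit_rows <- list(); truth_rows <- list()
  for (leaf in tree$phylo$tip.label) {
    type <- scenario$types[[leaf]]
    rec_id <- if (type == "2") paste0(leaf, "_L") else leaf
    mods <- modules_of(type)
    pieces <- vapply(mods, function(m) leafseq[[m]][[leaf]], "")
    ends <- cumsum(nchar(pieces))
    starts <- ends - nchar(pieces) + 1L
    ann <- mods %in% annotated
    seq_rows[[rec_id]] <- tibble(id = rec_id,
                                 residues = paste(pieces, collapse = ""),
                                 description = paste0("synthetic DA type ",
                                                      type))
    hit_rows[[rec_id]] <- tibble(seq_id = rec_id, domain = mods[ann],
                                 env_start = as.integer(starts[ann]),
                                 env_end = as.integer(ends[ann]),
                                 model_coverage = config$base_coverage,
                                 source = "synthetic")
    subtype <- switch(type, "1" = "1", "2" = "2", "3" = "3-canonical",
                      "4" = "4", "5" = "5-BIG1")
    partner <- if (type == "2") paste0(leaf, "_M") else NA_character_
    truth_rows[[rec_id]] <- tibble(seq_id = rec_id, leaf = leaf,
                                   da_type = type, subtype = subtype,
                                   partner = partner)
    if (type == "2") {
      mid <- paste0(leaf, "_M")
      mres <- leafseq[["Bgal_Small_N"]][[leaf]]
      seq_rows[[mid]] <- tibble(id = mid, residues = mres,
                                description = "synthetic LacM small subunit")
      hit_rows[[mid]] <- tibble(seq_id = mid, domain = "Bgal_Small_N",
                                env_start = 1L,
                                env_end = as.integer(nchar(mres)),
                                model_coverage = config$base_coverage,
                                source = "synthetic")
      truth_rows[[mid]] <- tibble(seq_id = mid, leaf = leaf,
                                  da_type = "lacM", subtype = "lacM",
                                  partner = rec_id)
    }
  }
  sequences <- bind_rows(seq_rows)
  truth_hits <- bind_rows(hit_rows)
  truth <- bind_rows(truth_rows)

  # true tree over GH2C-bearing records
  phy2 <- tree$phylo
  phy2$tip.label <- vapply(phy2$tip.label, function(lf) {
    if (scenario$types[[lf]] == "2") paste0(lf, "_L") else lf
  }, "")
  true_tree <- new_gh2_tree(phy2, meta = tree$meta)

  # annotation noise, applied after the truth is frozen
  hits <- truth_hits
  if (config$dropout > 0) {
    hits <- hits[runif(nrow(hits)) >= config$dropout, ]
  }
  if (config$jitter > 0) {
    hits$model_coverage <- pmin(1, pmax(0, hits$model_coverage +
                                          runif(nrow(hits), -config$jitter,
                                                config$jitter)))
  }
  gh2c_ids <- sort(unique(hits$seq_id[hits$domain == "GH2C"]))
  contam <- character(0)
  if (config$hybrid_count > 0) {
    contam <- sort(sample(gh2c_ids, min(config$hybrid_count,
                                        length(gh2c_ids))))
    len <- setNames(nchar(sequences$residues), sequences$id)
    hits <- bind_rows(hits, tibble(
      seq_id = contam, domain = "PKinase",
      env_start = as.integer(pmax(1, len[contam] - 49)),
      env_end = as.integer(len[contam]),
      model_coverage = 0.9, source = "contaminant"))
  }
  if (config$duplicate_gh2c_count > 0) {
    pool <- setdiff(gh2c_ids, contam)
    dup <- sort(sample(pool, min(config$duplicate_gh2c_count, length(pool))))
    first <- hits |> filter(.data$domain == "GH2C", .data$seq_id %in% dup)
    hits <- bind_rows(hits, first |>
                        mutate(env_start = .data$env_start + 5L,
                               source = "contaminant"))
  }
  hits <- arrange(hits, .data$seq_id, .data$env_start, .data$domain)

  planted_ids <- truth$seq_id[truth$leaf %in%
                                clade_sets(tree$phylo)[[
                                  unname(scenario$nodes["type5"]) -
                                    config$n_taxa]] &
                                truth$da_type != "lacM"]
  structure(list(
    sequences = sequences, hits = hits, truth_hits = truth_hits,
    truth = truth,
    partners = truth |> filter(!is.na(.data$partner),
                               .data$da_type != "lacM") |>
      select("seq_id", "partner"),
    tree = true_tree,
    big1_ref = tibble(id = "BIG1_ref", residues = roots[["BIG1"]]),
    planted = list(positions = config$planted_positions,
                   clade_records = sort(planted_ids)),
    scenario = scenario, config = config),
    class = "gh2_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits exactly the formats the readers consume; identical config and seed
#' give byte-identical files.
#'
#' @param sim A `gh2_sim` from [simulate_gh2()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$sequences, file.path(dir, "sequences.fasta"))
  write_domain_table(sim$hits, file.path(dir, "domains.tsv"))
  write_domain_table(sim$truth_hits, file.path(dir, "truth_domains.tsv"))
  readr::write_tsv(sim$partners, file.path(dir, "partners.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_fasta(sim$big1_ref, file.path(dir, "big1_ref.fasta"))
  readr::write_tsv(tibble(module = "GH2C",
                          position = sim$planted$positions),
                   file.path(dir, "planted.tsv"))
  cfg <- unclass(sim$config)
  cfg$module_lengths <- as.list(cfg$module_lengths)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Extract catalytic-domain regions
#'
#' Substrings each sequence's GH2C envelope for the phylogeny stage;
#' sequences without a single GH2C hit are omitted.
#'
#' @param seqs Sequence tibble.
#' @param hits Domain-hit tibble.
#' @param config A [gh2_config()].
#' @return Tibble with `id`, `residues` (GH2C regions).
#' @export
gh2c_sequences <- function(seqs, hits, config = gh2_config()) {
  g <- hits |>
    filter(.data$domain == config$core_gh2c) |>
    group_by(.data$seq_id) |>
    filter(dplyr::n() == 1) |>
    ungroup()
  seqs |>
    dplyr::inner_join(g, by = c(id = "seq_id")) |>
    mutate(residues = substr(.data$residues, .data$env_start,
                             .data$env_end)) |>
    select("id", "residues")
}
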
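#' Describe a synthetic gut-community study design
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a flock of broilers from which low and high body-weight (BW)
#' birds are drawn beyond one standard deviation of the flock mean, each
#' bird sampled in three gut compartments (jejunum chymus JC, jejunum
#' mucosa JM, caecum chymus CC), compositional genus counts with
#' per-sample sequencing depth, optional planted co-occurring genus blocks
#' (a shared per-bird latent factor on the log scale) and optional planted
#' BW effects (log2 fold change per BW standard deviation, applied to each
#' bird's standardised weight).
#'
#' @param n_birds_per_group birds per BW group (>= 3).
#' @param places compartment labels.
#' @param n_genera number of genera simulated.
#' @param depth_range integer pair; per-sample depth is uniform on it.
#' @param bw_population_mean_g,bw_population_sd_g flock body-weight
#'   distribution (grams).
#' @param bw_population_n flock size the BW selection draws from.
#' @param planted_blocks list of blocks, each a list with `places`
#'   (character), `genera` (feature ids), `loading` (>= 0) and optional
#'   `bw_group` restricting the block to one BW group.
#' @param planted_bw_effects list of effects, each a list with `place`,
#'   `genus`, `l2fc` (log2 fold change per BW standard deviation).
#' @param dispersion total Dirichlet concentration; smaller values give
#'   more overdispersed (noisier) compositions. The default keeps the
#'   counting layer subordinate to the log-normal biological noise so
#'   that planted latent structure survives into the counts.
#' @param baseline_sdlog sd of log genus baselines (taxon inequality).
#' @param place_sdlog sd of genus-by-compartment offsets (compartment
#'   separation; drives beta-diversity signal).
#' @param noise_sdlog residual per-sample log-normal noise.
#' @param seed master seed.
#' @return a validated list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_birds_per_group = 5,
                             places = PLACES,
                             n_genera = 30,
                             depth_range = c(12000L, 20000L),
                             bw_population_mean_g = 2696,
                             bw_population_sd_g = 227,
                             bw_population_n = 160,
                             planted_blocks = list(),
                             planted_bw_effects = list(),
                             dispersion = 50000,
                             baseline_sdlog = 1,
                             place_sdlog = 1,
                             noise_sdlog = 0.15,
                             seed = 1L) {
  design <- list(n_birds_per_group = as.integer(n_birds_per_group),
                 places = places,
                 n_genera = as.integer(n_genera),
                 depth_range = as.integer(depth_range),
                 bw_population_mean_g = bw_population_mean_g,
                 bw_population_sd_g = bw_population_sd_g,
                 bw_population_n = as.integer(bw_population_n),
                 planted_blocks = planted_blocks,
                 planted_bw_effects = planted_bw_effects,
                 dispersion = dispersion,
                 baseline_sdlog = baseline_sdlog,
                 place_sdlog = place_sdlog,
                 noise_sdlog = noise_sdlog,
                 seed = as.integer(seed))
  if (design$n_birds_per_group < 3L) {
    stop_located("n_birds_per_group must be >= 3")
  }
  if (length(design$depth_range) != 2L || any(design$depth_range <= 0) ||
      design$depth_range[1L] > design$depth_range[2L]) {
    stop_located("depth_range must be a positive ordered pair")
  }
  if (design$n_genera < 2L) stop_located("n_genera must be >= 2")
  if (design$dispersion <= 0) stop_located("dispersion must be > 0")
  ids <- genus_ids(design$n_genera)
  for (b in design$planted_blocks) {
    if (is.null(b$places) || is.null(b$genera) || is.null(b$loading)) {
      stop_located("each planted block needs places, genera and loading")
    }
    if (b$loading < 0) stop_located("block loading must be >= 0")
    if (!all(b$places %in% design$places)) {
      stop_located("block places must be a subset of the design places")
    }
    if (!all(b$genera %in% ids)) {
      stop_located("block genera must be among the simulated genus ids")
    }
  }
  # planted genus sets must be disjoint within a compartment
  for (pl in design$places) {
    seen <- character(0)
    for (b in design$planted_blocks) {
      if (!(pl %in% b$places)) next
      if (length(intersect(seen, b$genera))) {
        stop_located("planted blocks overlap within compartment %s", pl)
      }
      seen <- c(seen, b$genera)
    }
  }
  for (e in design$planted_bw_effects) {
    if (is.null(e$place) || is.null(e$genus) || is.null(e$l2fc)) {
      stop_located("each planted BW effect needs place, genus and l2fc")
    }
    if (!(e$place %in% design$places) || !(e$genus %in% ids)) {
      stop_located("BW effect refers to unknown place or genus")
    }
  }
  class(design) <- "synthetic_design"
  design
}

genus_ids <- function(n) sprintf("g%03d", seq_len(n))

#' Simulate flock body weights and the tail-selection of study birds
#'
#' Draws a normal flock of `n_population` weights and selects `n_low`
#' birds below `mean - sd` and `n_high` above `mean + sd`, the selection
#' rule used to form low/high body-weight groups. If a tail holds too few
#' birds the flock is redrawn (bounded retries).
#'
#' @param n_population flock size.
#' @param mean,sd flock mean and standard deviation in grams (`sd > 0`).
#' @param n_low,n_high birds to select per tail.
#' @param seed integer seed.
#' @param max_retries flock redraws allowed before giving up.
#' @return list with numeric vectors `low` and `high`.
#' @export
simulate_body_weights <- function(n_population = 160, mean = 2696, sd = 227,
                                  n_low = 5, n_high = 5, seed = 1L,
                                  max_retries = 100L) {
  if (sd <= 0) {
    stop_located("sd must be > 0: a degenerate flock has no selectable tails")
  }
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_retries)) {
      w <- stats::rnorm(n_population, mean, sd)
      lo <- w[w < mean - sd]
      hi <- w[w > mean + sd]
      if (length(lo) >= n_low && length(hi) >= n_high) {
        return(list(low = sample(lo, n_low), high = sample(hi, n_high)))
      }
    }
    stop_located(
      "tails of the flock too small for the requested selection after %d redraws",
      max_retries)
  })
}

#' Simulate a compartmentalised genus count table with ground truth
#'
#' One sample per bird and compartment. Genus relative abundances come
#' from log-normal baselines plus genus-by-compartment offsets; genera of
#' a planted block share a per-bird latent factor scaled by the block
#' loading; planted BW effects act multiplicatively as
#' `2^(l2fc * standardised body weight)`. Counts are drawn by a
#' Dirichlet-multinomial at a per-sample depth uniform on `depth_range`,
#' so column sums equal the drawn depths exactly.
#'
#' Planted-block genera take their baselines from the upper half of the
#' baseline distribution (the absolute value of the log-normal draw):
#' co-occurring communities are only discoverable among genera that
#' survive the prevalence filter, so planting one on a genus expected at
#' a handful of reads would make recovery ill-posed rather than hard.
#'
#' @param design a [synthetic_design()].
#' @return list with `counts` (integer matrix genera x samples), `meta`
#'   (sample frame), `taxonomy` (7-rank map) and `truth` (bird weights,
#'   per-compartment true edges, true BW-associated genera).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  nb <- design$n_birds_per_group
  ids <- genus_ids(design$n_genera)

  bw <- simulate_body_weights(design$bw_population_n,
                              design$bw_population_mean_g,
                              design$bw_population_sd_g,
                              n_low = nb, n_high = nb,
                              seed = child_seed(design$seed, "bw"))
  birds <- data.frame(
    bird_id = c(sprintf("LBW_b%d", seq_len(nb)), sprintf("HBW_b%d", seq_len(nb))),
    bw_group = rep(BW_GROUPS, each = nb),
    body_weight_g = c(bw$low, bw$high),
    stringsAsFactors = FALSE)
  birds$std_bw <- (birds$body_weight_g - design$bw_population_mean_g) /
    design$bw_population_sd_g

  meta <- expand.grid(bird = seq_len(nrow(birds)),
                      place = design$places,
                      stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = paste(meta$place, birds$bird_id[meta$bird], sep = "_"),
    bird_id = birds$bird_id[meta$bird],
    place = meta$place,
    bw_group = birds$bw_group[meta$bird],
    body_weight_g = birds$body_weight_g[meta$bird],
    stringsAsFactors = FALSE)

  ngen <- design$n_genera
  base <- withr::with_seed(child_seed(design$seed, "baseline"),
                           stats::rnorm(ngen, 0, design$baseline_sdlog))
  # planted-block genera draw from the detectable half of the baseline
  # distribution: a co-occurring community must be observable under the
  # prevalence filter to be a meaningful recovery target
  planted <- unique(unlist(lapply(design$planted_blocks, `[[`, "genera")))
  if (length(planted)) {
    gi <- match(planted, ids)
    base[gi] <- abs(base[gi])
  }
  place_off <- withr::with_seed(
    child_seed(design$seed, "place"),
    matrix(stats::rnorm(ngen * length(design$places), 0, design$place_sdlog),
           ngen, length(design$places),
           dimnames = list(ids, design$places)))
  latents <- withr::with_seed(
    child_seed(design$seed, "latent"),
    matrix(stats::rnorm(length(design$planted_blocks) * nrow(birds)),
           nrow = max(1L, length(design$planted_blocks)), ncol = nrow(birds)))

  counts <- matrix(0L, ngen, nrow(meta), dimnames = list(ids, meta$sample_id))
  withr::with_seed(child_seed(design$seed, "counts"), {
    for (s in seq_len(nrow(meta))) {
      bird_row <- match(meta$bird_id[s], birds$bird_id)
      pl <- meta$place[s]
      logab <- base + place_off[, pl] +
        stats::rnorm(ngen, 0, design$noise_sdlog)
      for (bi in seq_along(design$planted_blocks)) {
        b <- design$planted_blocks[[bi]]
        if (!(pl %in% b$places)) next
        if (!is.null(b$bw_group) && b$bw_group != meta$bw_group[s]) next
        gi <- match(b$genera, ids)
        logab[gi] <- logab[gi] + b$loading * latents[bi, bird_row]
      }
      for (e in design$planted_bw_effects) {
        if (e$place != pl) next
        gi <- match(e$genus, ids)
        logab[gi] <- logab[gi] + log(2) * e$l2fc * birds$std_bw[bird_row]
      }
      rel <- exp(logab - max(logab))
      rel <- rel / sum(rel)
      depth <- sample(design$depth_range[1L]:design$depth_range[2L], 1L)
      p <- stats::rgamma(ngen, shape = design$dispersion * rel)
      if (sum(p) <= 0) p <- rel            # pathological dispersion guard
      counts[, s] <- stats::rmultinom(1L, depth, p / sum(p))[, 1L]
    }
  })

  truth <- list(
    bird_weights = stats::setNames(birds$body_weight_g, birds$bird_id),
    true_edges = synthetic_true_edges(design),
    true_bw_genera = lapply(design$planted_bw_effects, function(e) {
      list(place = e$place, genus = e$genus, sign = sign(e$l2fc))
    }))

  list(counts = counts,
       meta = meta,
       taxonomy = synthetic_taxonomy(design),
       truth = truth)
}

# All unordered within-block genus pairs, per compartment the block acts in.
synthetic_true_edges <- function(design) {
  out <- list()
  for (pl in design$places) {
    pairs <- list()
    for (b in design$planted_blocks) {
      if (!(pl %in% b$places) || b$loading <= 0) next
      g <- sort(b$genera)
      if (length(g) < 2L) next
      cmb <- utils::combn(g, 2L)
      pairs <- c(pairs, lapply(seq_len(ncol(cmb)), function(k) cmb[, k]))
    }
    out[[pl]] <- pairs
  }
  out
}

# Deterministic synthetic lineages over a fixed phylum pool so that
# phylum-level operations (aggregation, B/F ratio) are exercised.
synthetic_taxonomy <- function(design) {
  ids <- genus_ids(design$n_genera)
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Cyanobacteria", "Tenericutes")
  ph <- withr::with_seed(
    child_seed(design$seed, "taxonomy"),
    sample(phyla, design$n_genera, replace = TRUE,
           prob = c(0.45, 0.25, 0.1, 0.1, 0.05, 0.05)))
  data.frame(feature_id = ids,
             kingdom = "Bacteria",
             phylum = ph,
             class = paste0(ph, "_class"),
             order = paste0(ph, "_order"),
             family = paste0(ph, "_family"),
             genus = paste0("Genus_", sub("^g", "", ids)),
             species = "Unclassified",
             stringsAsFactors = FALSE)
}

#' Simulate a rooted phylogeny over taxon ids
#'
#' Either a random rooted binary tree with uniform branch lengths or a
#' star tree with unit branches (handy as a closed-form Faith's PD case).
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed (random type only).
#' @param type `"random"` or `"star"`.
#' @param tip_labels leaf names; defaults to the simulator's genus ids.
#' @return a rooted `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, type = c("random", "star"),
                          tip_labels = genus_ids(n_taxa)) {
  type <- match.arg(type)
  if (n_taxa < 2L) stop_located("a tree needs at least 2 taxa")
  stopifnot(length(tip_labels) == n_taxa)
  if (type == "star") {
    tree <- ape::stree(n_taxa, type = "star", tip.label = tip_labels)
    tree$edge.length <- rep(1, nrow(tree$edge))
    tree$root.edge <- 0   # mark the basal polytomy as a genuine root
    return(tree)
  }
  withr::with_seed(as.integer(seed),
                   ape::rtree(n_taxa, rooted = TRUE, tip.label = tip_labels))
}

#' Write a simulated dataset to disk in the formats the readers accept
#'
#' Counts, metadata and taxonomy as TSV, the truth object as JSON, and
#' (optionally) a tree as Newick.
#'
#' @param sim output of [simulate_counts()].
#' @param dir output directory (created if missing).
#' @param tree optional `phylo` object.
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic <- function(sim, dir, tree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(sim$counts, paths[["counts"]])
  write_metadata(sim$meta, paths[["meta"]])
  write_taxonomy(sim$taxonomy, paths[["taxonomy"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(tree)) {
    paths[["tree"]] <- file.path(dir, "tree.nwk")
    ape::write.tree(tree, paths[["tree"]])
  }
  invisible(paths)
}
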
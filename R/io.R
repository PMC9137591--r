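#' Read a feature-by-sample count table from TSV
#'
#' The expected layout is the common amplicon convention: features as rows,
#' one header row of sample ids, first column holding feature ids. Every
#' cell must be a non-negative integer; validation failures name the
#' offending row and column rather than silently coercing.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix (features x samples) with feature rownames and
#'   sample colnames.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_located("empty count table file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (!length(sample_ids)) stop_located("count table has no sample columns")
  if (anyDuplicated(sample_ids)) {
    stop_located("duplicate sample id in header: %s",
                 sample_ids[duplicated(sample_ids)][1L])
  }
  ncol_expect <- length(header)
  body <- fields[-1L]
  feature_ids <- character(length(body))
  counts <- matrix(0L, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expect) {
      stop_located("ragged row %d ('%s'): %d fields, expected %d",
                   i + 1L, row[1L], length(row), ncol_expect)
    }
    feature_ids[i] <- row[1L]
    vals <- row[-1L]
    bad <- !grepl("^[0-9]+$", vals)
    if (any(bad)) {
      j <- which(bad)[1L]
      stop_located("non-integer count '%s' at feature '%s', sample '%s'",
                   vals[j], row[1L], sample_ids[j])
    }
    counts[i, ] <- as.integer(vals)
  }
  if (anyDuplicated(feature_ids)) {
    stop_located("duplicate feature id: %s",
                 feature_ids[duplicated(feature_ids)][1L])
  }
  dimnames(counts) <- list(feature_ids, sample_ids)
  counts
}

#' Write a count table as TSV (inverse of [read_count_table()])
#'
#' @param counts integer matrix, features x samples.
#' @param path output path.
#' @param id_column header name of the feature-id column.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  assert_count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = "\t"))
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Required columns: `sample_id`, `bird_id`, `place` (JC/JM/CC), `bw_group`
#' (LBW/HBW), `body_weight_g` (> 0). Unknown labels and non-positive
#' weights are rejected.
#'
#' @param path path to a tab-separated file with a header row.
#' @return a validated data.frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  meta <- assert_sample_frame(meta)
  meta$place <- factor(meta$place, levels = PLACES)
  meta$bw_group <- factor(meta$bw_group, levels = BW_GROUPS)
  meta
}

#' Write sample metadata as TSV
#' @param meta metadata data.frame (see [read_metadata()]).
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  assert_sample_frame(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two tab-separated columns: feature id and a semicolon-separated lineage.
#' Optional QIIME-style rank prefixes (`k__`, `p__`, ..., `s__`) are
#' stripped. Lineages shorter than seven ranks are padded with
#' `"Unclassified"`; features absent from the map are treated as
#' `"Unclassified"` at every rank by the aggregation step (they are kept,
#' not dropped, mirroring partially classified amplicon data).
#'
#' @param path path to the TSV.
#' @return data.frame with columns `feature_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  first <- fields[[1L]]
  if (length(first) >= 1L && tolower(first[1L]) %in% c("feature_id", "otu_id", "id")) {
    fields <- fields[-1L]
  }
  ids <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop_located("duplicate feature id in taxonomy: %s",
                 ids[duplicated(ids)][1L])
  }
  lineages <- vapply(fields, function(f) {
    if (length(f) < 2L) stop_located("feature '%s' has no lineage field", f[1L])
    f[2L]
  }, character(1L))
  parse_one <- function(lin, id) {
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1L]])
    parts <- sub("^[kpcofgs]__", "", parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) > length(TAX_RANKS)) {
      stop_located("lineage of '%s' has %d ranks (max %d)", id,
                   length(parts), length(TAX_RANKS))
    }
    c(parts, rep("Unclassified", length(TAX_RANKS) - length(parts)))
  }
  mat <- t(mapply(parse_one, lineages, ids))
  tax <- data.frame(feature_id = ids, mat, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(tax) <- c("feature_id", TAX_RANKS)
  tax
}

#' Write a taxonomy map as TSV
#' @param tax taxonomy data.frame from [read_taxonomy()] or the simulator.
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(tax[, TAX_RANKS, drop = FALSE], 1L, paste, collapse = ";")
  utils::write.table(
    data.frame(feature_id = tax$feature_id, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @param require_rooted error if the tree is unrooted (needed for Faith's
#'   PD).
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree_file <- function(path, require_rooted = FALSE) {
  txt <- paste(readLines(path), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) {
    stop_located("Newick parse error: missing terminal ';' in %s", path)
  }
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop_located("Newick parse error in %s", path)
  if (require_rooted && !ape::is.rooted(tree)) {
    stop_located("tree in %s is unrooted but a rooted tree is required", path)
  }
  tree
}

#' Analysis configuration with field-standard defaults
#'
#' Thresholds mirror common practice for rarefied 16S genus tables from
#' small designs: rarefaction to 10,000 reads, a 10-read minimum feature
#' total, Shannon in log base 2, 999 permutations for distance-based tests,
#' a 4-of-5 prevalence rule and |rho| >= 0.9 edge rule with 1,000 Monte
#' Carlo replicates for the co-occurrence networks, and a > 0.01% mean
#' abundance plus >= 8-sample inclusion rule for the body-weight screen.
#'
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param min_feature_reads minimum feature total across all samples.
#' @param shannon_log_base base of the Shannon index logarithm.
#' @param n_permutations permutations for PERMANOVA/ANOSIM/CCA.
#' @param cooc_prevalence_min samples (out of the group's, typically 5) in
#'   which a genus must be non-zero to enter a network.
#' @param cooc_edge_rho_min |rho| threshold for calling an edge.
#' @param cooc_allow_negative call negative edges at rho <= -threshold.
#' @param cooc_mc_reps Monte Carlo replicates for degree/component tests.
#' @param trait_min_mean_pct minimum mean relative abundance (%) for the
#'   body-weight screen.
#' @param trait_min_prevalence minimum samples with non-zero abundance for
#'   the body-weight screen.
#' @param alpha significance level.
#' @param trend_band FDR p interval reported as a trend.
#' @param seed master seed; all stage seeds derive from it.
#' @return a list of class `gutcooc_config`.
#' @export
gutcooc_config <- function(rarefaction_depth = 10000,
                           min_feature_reads = 10,
                           shannon_log_base = 2,
                           n_permutations = 999,
                           cooc_prevalence_min = 4,
                           cooc_edge_rho_min = 0.9,
                           cooc_allow_negative = TRUE,
                           cooc_mc_reps = 1000,
                           trait_min_mean_pct = 0.01,
                           trait_min_prevalence = 8,
                           alpha = 0.05,
                           trend_band = c(0.05, 0.10),
                           seed = 1L) {
  cfg <- list(rarefaction_depth = rarefaction_depth,
              min_feature_reads = min_feature_reads,
              shannon_log_base = shannon_log_base,
              n_permutations = n_permutations,
              cooc_prevalence_min = cooc_prevalence_min,
              cooc_edge_rho_min = cooc_edge_rho_min,
              cooc_allow_negative = isTRUE(cooc_allow_negative),
              cooc_mc_reps = cooc_mc_reps,
              trait_min_mean_pct = trait_min_mean_pct,
              trait_min_prevalence = trait_min_prevalence,
              alpha = alpha,
              trend_band = trend_band,
              seed = as.integer(seed))
  stopifnot(cfg$rarefaction_depth >= 1, cfg$min_feature_reads >= 0,
            cfg$shannon_log_base > 1, cfg$n_permutations >= 1,
            cfg$cooc_prevalence_min >= 0,
            cfg$cooc_edge_rho_min > 0, cfg$cooc_edge_rho_min <= 1.01,
            cfg$cooc_mc_reps >= 100,
            cfg$trait_min_mean_pct >= 0, cfg$trait_min_prevalence >= 2,
            cfg$alpha > 0, cfg$alpha < 1,
            length(cfg$trend_band) == 2L,
            cfg$trend_band[1L] <= cfg$trend_band[2L])
  class(cfg) <- "gutcooc_config"
  cfg
}

#' Read a YAML configuration file
#'
#' Unknown keys are rejected; missing keys take the [gutcooc_config()]
#' defaults.
#' @param path path to a YAML file.
#' @return a `gutcooc_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(gutcooc_config))
  extra <- setdiff(names(vals), c(known, "simulate", "design"))
  if (length(extra)) {
    stop_located("unknown config key(s): %s", paste(extra, collapse = ", "))
  }
  cfg <- do.call(gutcooc_config, vals[intersect(names(vals), known)])
  cfg$simulate <- isTRUE(vals$simulate)
  cfg$design <- vals$design
  cfg
}

# Generic TSV writer for result data frames.
write_result_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes an edge-list TSV, a per-node TSV (degree and, when present,
#' Monte Carlo degree p), and a GraphML file.
#'
#' @param network a `group_network` or `cross_network` object.
#' @param prefix output path prefix (files get `_edges.tsv`, `_nodes.tsv`,
#'   `.graphml` suffixes).
#' @export
write_network <- function(network, prefix) {
  edges <- network$edges
  write_result_tsv(edges, paste0(prefix, "_edges.tsv"))
  gedges <- edges[, intersect(c("genus_a", "genus_b", "rho", "sign"),
                              names(edges)), drop = FALSE]
  if (inherits(network, "cross_network")) {
    # bipartite over the same genus universe: prefix vertices by side so a
    # genus present in both compartments yields two distinct nodes
    nodes <- data.frame(
      name = c(paste0(network$from, ":", network$from_nodes),
               paste0(network$to, ":", network$to_nodes)),
      genus = c(network$from_nodes, network$to_nodes),
      side = c(rep(network$from, length(network$from_nodes)),
               rep(network$to, length(network$to_nodes))),
      stringsAsFactors = FALSE)
    nodes$degree <- ifelse(nodes$side == network$from,
                           as.integer(network$degree[nodes$genus]), NA)
    if (nrow(gedges)) {
      gedges$genus_a <- paste0(network$from, ":", gedges$genus_a)
      gedges$genus_b <- paste0(network$to, ":", gedges$genus_b)
    }
  } else {
    nodes <- data.frame(name = names(network$degree),
                        genus = names(network$degree),
                        degree = as.integer(network$degree),
                        stringsAsFactors = FALSE)
  }
  if (!is.null(network$mc_degree_p)) {
    p <- network$mc_degree_p[nodes$genus]
    p[!is.na(nodes$degree) & is.na(p)] <- NA
    if (inherits(network, "cross_network")) {
      p[nodes$side != network$from] <- NA
    }
    nodes$mc_degree_p <- as.numeric(p)
  }
  write_result_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  g <- igraph::graph_from_data_frame(gedges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}
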
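# End-to-end orchestration: filter -> rarefy -> aggregate -> diversity ->
# ordination -> composition screen -> trait screen -> networks -> report.

#' Run the full analysis pipeline
#'
#' Executes every stage in order on either supplied input files or a
#' simulated dataset, writes all result tables under `out_dir`, and
#' returns (and saves) a run manifest with the configuration snapshot,
#' input digests, per-stage seeds and output paths. Reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config a `gutcooc_config`, or the path to a YAML config file.
#'   Set `config$simulate = TRUE` to run on a simulated dataset (an
#'   optional `config$design` list overrides [synthetic_design()]
#'   defaults).
#' @param out_dir output directory (created if needed).
#' @param counts,taxonomy,metadata,tree input file paths (ignored in
#'   simulate mode).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         counts = NULL, taxonomy = NULL, metadata = NULL,
                         tree = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "gutcooc_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  inputs <- list()
  tre <- NULL
  if (isTRUE(config$simulate)) {
    design_args <- config$design %||% list()
    design_args$seed <- design_args$seed %||% config$seed
    design <- stage("simulate", do.call(synthetic_design, design_args))
    sim <- stage("simulate", simulate_counts(design))
    tre <- simulate_tree(design$n_genera,
                         seed = child_seed(design$seed, "tree"))
    paths <- write_synthetic(sim, file.path(out_dir, "inputs"), tree = tre)
    cnt <- sim$counts; tax <- sim$taxonomy; meta <- sim$meta
    inputs <- as.list(paths)
  } else {
    if (is.null(counts) || is.null(metadata)) {
      stop_located("counts and metadata paths are required unless simulate = TRUE")
    }
    cnt <- stage("read", read_count_table(counts))
    meta <- stage("read", read_metadata(metadata))
    tax <- if (!is.null(taxonomy)) stage("read", read_taxonomy(taxonomy)) else NULL
    tre <- if (!is.null(tree)) stage("read", read_tree_file(tree, require_rooted = TRUE)) else NULL
    inputs <- list(counts = counts, metadata = metadata,
                   taxonomy = taxonomy, tree = tree)
  }
  missing_meta <- setdiff(colnames(cnt), meta$sample_id)
  if (length(missing_meta)) {
    stop_located("pipeline stage 'validate' failed: sample(s) absent from metadata: %s",
                 paste(missing_meta, collapse = ", "))
  }
  meta <- assert_sample_frame(meta)

  # --- filtering and rarefaction -------------------------------------------
  filtered <- stage("filter",
                    filter_low_abundance(cnt, config$min_feature_reads))
  rare <- stage("rarefy",
                rarefy_counts(filtered, config$rarefaction_depth,
                              seed = child_seed(config$seed, "rarefy")))
  meta_r <- meta[match(colnames(rare), meta$sample_id), ]
  write_count_table(rare, file.path(out_dir, "rarefied_counts.tsv"))

  # --- diversity ------------------------------------------------------------
  alpha <- stage("alpha_diversity",
                 alpha_diversity(rare, tree = tre,
                                 log_base = config$shannon_log_base))
  write_result_tsv(round_df(alpha), file.path(out_dir, "alpha_diversity.tsv"))

  # --- aggregation and relative abundance ----------------------------------
  genus <- if (!is.null(tax)) stage("aggregate", aggregate_to_rank(rare, tax, "genus")) else rare
  phylum <- if (!is.null(tax)) stage("aggregate", aggregate_to_rank(rare, tax, "phylum")) else NULL
  rel_genus <- stage("relative", to_relative(genus))
  write_result_tsv(round_df(mat_to_df(rel_genus, "genus")),
                   file.path(out_dir, "relative_genus.tsv"))

  # --- ordination ------------------------------------------------------------
  bc <- stage("ordination", bray_curtis(rel_genus))
  write_result_tsv(round_df(mat_to_df(bc, "sample_id")),
                   file.path(out_dir, "bray_curtis.tsv"))
  ord <- stage("ordination", pcoa_ordination(bc))
  write_result_tsv(round_df(mat_to_df(ord$coordinates, "sample_id")),
                   file.path(out_dir, "pcoa_coordinates.tsv"))
  tests <- list(
    permanova_place = stage("ordination",
      permanova(bc, meta_r$place, config$n_permutations,
                seed = child_seed(config$seed, "permanova_place"))),
    permanova_bw = stage("ordination",
      permanova(bc, meta_r$bw_group, config$n_permutations,
                seed = child_seed(config$seed, "permanova_bw"))),
    anosim_place = stage("ordination",
      anosim_test(bc, meta_r$place, config$n_permutations,
                  seed = child_seed(config$seed, "anosim_place"))),
    anosim_bw = stage("ordination",
      anosim_test(bc, meta_r$bw_group, config$n_permutations,
                  seed = child_seed(config$seed, "anosim_bw"))))
  cca_fit <- stage("ordination",
    cca_constrained(rel_genus,
                    data.frame(bw_group = factor(meta_r$bw_group)),
                    config$n_permutations,
                    seed = child_seed(config$seed, "cca_bw")))
  tests$cca_bw <- cca_fit$test
  tests$cca_bw_inertia_fraction <- cca_fit$constrained_inertia_fraction
  jsonlite::write_json(lapply(tests, unclass),
                       file.path(out_dir, "ordination_tests.json"),
                       auto_unbox = TRUE, digits = 10)

  # --- composition ------------------------------------------------------------
  gm_genus <- stage("composition", group_mean_table(rel_genus, meta_r))
  write_result_tsv(round_df(as_group_mean_frame(gm_genus)),
                   file.path(out_dir, "group_means_genus.tsv"))
  screen_genus <- stage("composition", anova_screen(rel_genus, meta_r, config))
  write_result_tsv(round_df(screen_genus),
                   file.path(out_dir, "anova_screen_genus.tsv"))
  if (!is.null(phylum)) {
    rel_phylum <- to_relative(phylum)
    gm_phylum <- stage("composition", group_mean_table(rel_phylum, meta_r))
    write_result_tsv(round_df(as_group_mean_frame(gm_phylum)),
                     file.path(out_dir, "group_means_phylum.tsv"))
    screen_phylum <- stage("composition",
                           anova_screen(rel_phylum, meta_r, config))
    write_result_tsv(round_df(screen_phylum),
                     file.path(out_dir, "anova_screen_phylum.tsv"))
    if ("Firmicutes" %in% rownames(rel_phylum)) {
      bf <- stage("composition", bf_ratio(rel_phylum, meta_r))
      write_result_tsv(round_df(bf$group_means),
                       file.path(out_dir, "bf_ratio_group_means.tsv"))
    }
  }
  venn <- stage("composition", venn_unique_shared(rare, meta_r, by = "place"))
  jsonlite::write_json(venn, file.path(out_dir, "venn_place.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- trait screen ------------------------------------------------------------
  trait <- stage("trait", bw_correlation_screen(rel_genus, meta_r, config))
  write_result_tsv(round_df(trait),
                   file.path(out_dir, "bw_correlations.tsv"))

  # --- co-occurrence networks ---------------------------------------------------
  net_summaries <- list()
  for (pl in intersect(PLACES, unique(as.character(meta_r$place)))) {
    for (gr in intersect(BW_GROUPS, unique(as.character(meta_r$bw_group)))) {
      tag <- paste(pl, gr, sep = "_")
      net <- tryCatch(
        build_group_network(rel_genus, meta_r, pl, gr, config),
        error = function(e) NULL)
      if (is.null(net)) {
        net_summaries[[tag]] <- list(place = pl, bw_group = gr,
                                     skipped = TRUE)
        next
      }
      sd_net <- child_seed(config$seed, paste0("net_", tag))
      net$mc_degree_p <- mc_degree_significance(net, config$cooc_mc_reps,
                                                seed = sd_net)
      comp <- component_significance(net, config$cooc_mc_reps,
                                     seed = child_seed(config$seed,
                                                       paste0("comp_", tag)))
      write_network(net, file.path(out_dir, paste0("network_", tag)))
      write_result_tsv(round_df(comp),
                       file.path(out_dir,
                                 paste0("network_", tag, "_components.tsv")))
      net_summaries[[tag]] <- list(
        place = pl, bw_group = gr, skipped = FALSE,
        n_nodes = length(net$nodes), n_edges = nrow(net$edges),
        n_components = length(net$components),
        min_component_p = if (nrow(comp)) min(comp$p_value) else NA,
        significant_degree_genera =
          names(net$mc_degree_p)[net$mc_degree_p < config$alpha])
    }
  }
  for (gr in intersect(BW_GROUPS, unique(as.character(meta_r$bw_group)))) {
    tag <- paste0("JC_JM_", gr)
    xnet <- tryCatch(
      cross_compartment_network(rel_genus, meta_r, gr, config),
      error = function(e) NULL)
    if (is.null(xnet)) {
      net_summaries[[tag]] <- list(bw_group = gr, cross = TRUE,
                                   skipped = TRUE)
      next
    }
    xnet$mc_degree_p <- mc_degree_significance(
      xnet, config$cooc_mc_reps,
      seed = child_seed(config$seed, paste0("xnet_", gr)))
    write_network(xnet, file.path(out_dir, paste0("network_", tag)))
    net_summaries[[tag]] <- list(
      bw_group = gr, cross = TRUE, skipped = FALSE,
      n_from = length(xnet$from_nodes), n_to = length(xnet$to_nodes),
      n_edges = nrow(xnet$edges),
      significant_out_degree_genera =
        names(xnet$mc_degree_p)[xnet$mc_degree_p < config$alpha])
  }
  jsonlite::write_json(net_summaries,
                       file.path(out_dir, "network_summaries.json"),
                       auto_unbox = TRUE, digits = 10)

  # --- manifest & report --------------------------------------------------------
  manifest <- list(
    tool = "gutcooc",
    version = as.character(utils::packageVersion("gutcooc")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1L))],
    inputs = lapply(inputs[!vapply(inputs, is.null, logical(1L))],
                    function(p) list(
                      path = sub(paste0("^", out_dir, "/?"), "", p),
                      md5 = unname(tools::md5sum(p)))),
    stages = c("filter", "rarefy", "alpha_diversity", "aggregate",
               "ordination", "composition", "trait", "networks", "report"),
    outputs = sort(list.files(out_dir, recursive = TRUE)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  make_report(out_dir)
  invisible(manifest)
}

mat_to_df <- function(mat, id_col) {
  df <- data.frame(rownames(mat), mat, stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = NULL)
  names(df)[1L] <- id_col
  df
}

# Stable numeric formatting so that reruns are byte-identical.
round_df <- function(df, digits = 6) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], digits)
  }
  df
}

#' Assemble a human-readable markdown report from a completed run
#'
#' Mirrors the standard presentation of this analysis: the alpha
#' diversity table, the group-mean composition tables with FDR columns,
#' the body-weight correlation list, and one network section per
#' sampling-place x BW-group combination (plus the cross-compartment
#' networks), each stating "no edges" when empty. Regeneration is
#' idempotent.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return the report path, invisibly.
#' @export
make_report <- function(out_dir) {
  need <- c("alpha_diversity.tsv", "network_summaries.json")
  miss <- need[!file.exists(file.path(out_dir, need))]
  if (length(miss)) {
    stop_located("incomplete run: missing %s", paste(miss, collapse = ", "))
  }
  lines <- c("# gutcooc run report", "")
  tsv_section <- function(title, file) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) return(character(0))
    c(paste0("## ", title), "", "```", readLines(p), "```", "")
  }
  lines <- c(lines,
             tsv_section("Alpha diversity", "alpha_diversity.tsv"),
             tsv_section("Phylum group means", "group_means_phylum.tsv"),
             tsv_section("Phylum screen (two-way ANOVA, BH-FDR)",
                         "anova_screen_phylum.tsv"),
             tsv_section("Genus group means", "group_means_genus.tsv"),
             tsv_section("Genus screen (two-way ANOVA, BH-FDR)",
                         "anova_screen_genus.tsv"),
             tsv_section("Body-weight correlations", "bw_correlations.tsv"))
  nets <- jsonlite::read_json(file.path(out_dir, "network_summaries.json"))
  lines <- c(lines, "## Co-occurrence networks", "")
  for (tag in names(nets)) {
    s <- nets[[tag]]
    lines <- c(lines, paste0("### ", tag), "")
    if (isTRUE(s$skipped)) {
      lines <- c(lines, "network skipped (no genera passed the filter)", "")
    } else if ((s$n_edges %||% 0) == 0) {
      lines <- c(lines, "no edges", "")
    } else if (isTRUE(s$cross)) {
      lines <- c(lines, sprintf(
        "%d x %d genera, %d cross-compartment edge(s); significant out-degree: %s",
        s$n_from, s$n_to, s$n_edges,
        if (length(s$significant_out_degree_genera))
          paste(unlist(s$significant_out_degree_genera), collapse = ", ")
        else "none"), "")
    } else {
      lines <- c(lines, sprintf(
        "%d genera, %d edge(s), %d component(s); min component p = %s; significant degree: %s",
        s$n_nodes, s$n_edges, s$n_components,
        format(s$min_component_p %||% NA),
        if (length(s$significant_degree_genera))
          paste(unlist(s$significant_degree_genera), collapse = ", ")
        else "none"), "")
    }
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
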
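#' Spearman screen of genus abundance against individual body weight
#'
#' Within each sampling place, every genus whose mean relative abundance
#' across the place's samples exceeds `trait_min_mean_pct` (0.01% by
#' default) and which is non-zero in at least `trait_min_prevalence`
#' samples (8 by default) is correlated with the birds' individual body
#' weight in grams, both BW groups pooled. p-values are two-sided and
#' exact wherever feasible (see [exact_spearman()]); no multiplicity
#' adjustment is applied in this screen — raw p < alpha is flagged, a
#' deliberate (and documented) choice mirroring common practice for this
#' kind of exploratory correlation list.
#'
#' Excluded genera are kept in the output with a machine-readable
#' exclusion reason. A place with fewer samples than
#' `trait_min_prevalence` is skipped with a warning.
#'
#' @param rel matrix, genera x samples (percent relative abundance).
#' @param meta sample metadata.
#' @param config a [gutcooc_config()].
#' @return data.frame with columns place, genus, rho, p_value, n_samples,
#'   included, reason, significant.
#' @export
bw_correlation_screen <- function(rel, meta, config = gutcooc_config()) {
  assert_sample_frame(meta)
  m <- meta[match(colnames(rel), meta$sample_id), ]
  out <- list()
  for (pl in intersect(PLACES, unique(as.character(m$place)))) {
    idx <- which(as.character(m$place) == pl)
    if (length(idx) < config$trait_min_prevalence) {
      warning(sprintf(
        "place %s has %d sample(s), fewer than the %d required; screen skipped",
        pl, length(idx), config$trait_min_prevalence), call. = FALSE)
      next
    }
    weights <- m$body_weight_g[idx]
    for (g in rownames(rel)) {
      x <- rel[g, idx]
      reasons <- character(0)
      if (mean(x) <= config$trait_min_mean_pct) {
        reasons <- c(reasons, sprintf("mean_abundance<=%g%%",
                                      config$trait_min_mean_pct))
      }
      if (sum(x > 0) < config$trait_min_prevalence) {
        reasons <- c(reasons, sprintf("prevalence<%d",
                                      config$trait_min_prevalence))
      }
      if (length(reasons)) {
        out[[length(out) + 1L]] <- data.frame(
          place = pl, genus = g, rho = NA_real_, p_value = NA_real_,
          n_samples = length(idx), included = FALSE,
          reason = paste(reasons, collapse = ";"), significant = NA,
          stringsAsFactors = FALSE)
        next
      }
      es <- exact_spearman(x, weights)
      out[[length(out) + 1L]] <- data.frame(
        place = pl, genus = g, rho = es$rho, p_value = es$two_sided_p,
        n_samples = length(idx), included = TRUE, reason = "",
        significant = !is.na(es$two_sided_p) &&
          es$two_sided_p < config$alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop_located("no place had enough samples for the screen")
  do.call(rbind, out)
}
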
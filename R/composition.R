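#' Aggregate features to a taxonomic rank
#'
#' Features are summed by their label at the requested rank. Features
#' missing from the taxonomy, or labelled `"Unclassified"`, are pooled
#' under a single `"Unclassified"` row — kept, not dropped, since real
#' amplicon tables are only partially classified at genus level.
#'
#' @param counts matrix, features x samples.
#' @param tax taxonomy data.frame from [read_taxonomy()].
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @return matrix with one row per rank label; column sums are preserved.
#' @export
aggregate_to_rank <- function(counts, tax, rank = "genus") {
  rank <- match.arg(rank, TAX_RANKS)
  labels <- tax[[rank]][match(rownames(counts), tax$feature_id)]
  labels[is.na(labels) | !nzchar(labels)] <- "Unclassified"
  rowsum(counts, group = labels)
}

#' Convert counts to percentage relative abundance
#'
#' Each column is scaled to sum to 100 (the scale group-mean tables are
#' reported on).
#'
#' @param counts matrix, features x samples, positive column sums.
#' @return numeric matrix of percentages.
#' @export
to_relative <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    stop_located("zero-sum sample(s): %s",
                 paste(colnames(counts)[cs <= 0], collapse = ", "))
  }
  sweep(counts, 2L, cs, "/") * 100
}

#' Marginal means of a balanced place x BW-group cell-mean table
#'
#' Given per-taxon cell means over a balanced design, the margin over
#' sampling places within each BW group ("Mean (BW)") and over BW groups
#' within each place ("Mean (SP)") are the arithmetic means of the cells.
#' This is the margin logic of group-mean composition tables.
#'
#' @param cells 3-d array `taxa x places x bw_groups` of cell means.
#' @return list with matrices `mean_bw` (taxa x bw_groups) and `mean_sp`
#'   (taxa x places).
#' @export
cell_margin_means <- function(cells) {
  stopifnot(length(dim(cells)) == 3L)
  list(mean_bw = apply(cells, c(1L, 3L), mean),
       mean_sp = apply(cells, c(1L, 2L), mean))
}

#' Group-mean relative-abundance table with margins
#'
#' Cell means over birds for each (place, BW group) combination, plus the
#' margins of [cell_margin_means()]. Requires a balanced design with no
#' empty cell.
#'
#' @param rel matrix, taxa x samples (percent).
#' @param meta sample metadata.
#' @return list of class `group_mean_table` with `cells` (3-d array),
#'   `mean_bw` and `mean_sp`.
#' @export
group_mean_table <- function(rel, meta) {
  assert_sample_frame(meta)
  m <- meta[match(colnames(rel), meta$sample_id), ]
  if (any(is.na(m$sample_id))) stop_located("samples missing from metadata")
  places <- intersect(PLACES, unique(as.character(m$place)))
  groups <- intersect(BW_GROUPS, unique(as.character(m$bw_group)))
  tab <- table(m$place, m$bw_group)[places, groups, drop = FALSE]
  if (any(tab == 0L)) stop_located("empty place x bw_group cell")
  if (length(unique(as.vector(tab))) != 1L) {
    stop_located("design is unbalanced; group means assume equal cell sizes")
  }
  cells <- array(NA_real_, c(nrow(rel), length(places), length(groups)),
                 dimnames = list(rownames(rel), places, groups))
  for (pl in places) {
    for (gr in groups) {
      idx <- m$place == pl & m$bw_group == gr
      cells[, pl, gr] <- rowMeans(rel[, idx, drop = FALSE])
    }
  }
  margins <- cell_margin_means(cells)
  structure(list(cells = cells, mean_bw = margins$mean_bw,
                 mean_sp = margins$mean_sp),
            class = "group_mean_table")
}

#' Flatten a group-mean table to a data.frame
#'
#' One row per taxon and BW group holding the place cells and the BW
#' margin, mirroring the layout of published composition tables.
#'
#' @param gmt a [group_mean_table()].
#' @return data.frame.
#' @export
as_group_mean_frame <- function(gmt) {
  stopifnot(inherits(gmt, "group_mean_table"))
  places <- dimnames(gmt$cells)[[2L]]
  groups <- dimnames(gmt$cells)[[3L]]
  rows <- list()
  for (tx in dimnames(gmt$cells)[[1L]]) {
    for (gr in groups) {
      row <- data.frame(taxon = tx, bw_group = gr, stringsAsFactors = FALSE)
      for (pl in places) row[[pl]] <- gmt$cells[tx, pl, gr]
      row$mean_bw <- gmt$mean_bw[tx, gr]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  sp <- as.data.frame(gmt$mean_sp)
  sp$taxon <- rownames(gmt$mean_sp)
  attr(out, "mean_sp") <- sp
  out
}

#' Bacteroidetes/Firmicutes ratio
#'
#' Per-sample ratio of percentage abundances; group values are means of
#' the per-sample ratios (not ratios of group means — the two differ on
#' skewed data). Samples with zero Firmicutes are excluded with a
#' warning; absent Bacteroidetes gives a 0 ratio.
#'
#' @param rel_phylum matrix at phylum rank, taxa x samples (percent).
#' @param meta sample metadata.
#' @return list with `per_sample` (data.frame) and `group_means`
#'   (data.frame over place x bw_group).
#' @export
bf_ratio <- function(rel_phylum, meta) {
  assert_sample_frame(meta)
  b <- if ("Bacteroidetes" %in% rownames(rel_phylum)) {
    rel_phylum["Bacteroidetes", ]
  } else {
    warning("Bacteroidetes absent; B/F numerator is 0", call. = FALSE)
    stats::setNames(rep(0, ncol(rel_phylum)), colnames(rel_phylum))
  }
  if (!("Firmicutes" %in% rownames(rel_phylum))) {
    stop_located("Firmicutes row absent: B/F ratio undefined")
  }
  f <- rel_phylum["Firmicutes", ]
  ratio <- ifelse(f > 0, b / f, NA_real_)
  if (any(f <= 0)) {
    warning(sprintf("excluding %d sample(s) with zero Firmicutes from B/F",
                    sum(f <= 0)), call. = FALSE)
  }
  m <- meta[match(colnames(rel_phylum), meta$sample_id), ]
  per_sample <- data.frame(sample_id = colnames(rel_phylum),
                           place = as.character(m$place),
                           bw_group = as.character(m$bw_group),
                           bf_ratio = as.numeric(ratio),
                           stringsAsFactors = FALSE)
  gm <- stats::aggregate(bf_ratio ~ place + bw_group, per_sample, mean,
                         na.rm = TRUE)
  list(per_sample = per_sample, group_means = gm)
}

#' Two-factor composition screen with BH-FDR
#'
#' Per taxon: a two-way fixed-effects ANOVA of relative abundance on
#' sampling place, BW group and their interaction (balanced design, so
#' Type I sums of squares coincide with Type II); Tukey HSD letters on the
#' place factor; a one-way BW ANOVA within each place; and
#' Benjamini-Hochberg adjustment across taxa, one family per effect.
#' Adjusted p < `alpha` is "significant", inside `trend_band` a "trend".
#' Constant taxa are reported with `NA` p-values and excluded from the
#' FDR families.
#'
#' @param rel matrix, taxa x samples (percent).
#' @param meta sample metadata (balanced place x bw_group design, >= 2
#'   samples per cell).
#' @param config a [gutcooc_config()].
#' @param transform `"none"` (default) or `"arcsine"` for an
#'   arcsine-square-root transform of the percentage before fitting.
#' @return data.frame, one row per taxon, with raw and FDR p per effect,
#'   significance class, Tukey letters and within-place BW p-values.
#' @export
anova_screen <- function(rel, meta, config = gutcooc_config(),
                         transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  assert_sample_frame(meta)
  m <- meta[match(colnames(rel), meta$sample_id), ]
  place <- factor(as.character(m$place), levels = intersect(PLACES, m$place))
  bw <- factor(as.character(m$bw_group), levels = intersect(BW_GROUPS, m$bw_group))
  if (any(table(place, bw) < 2L)) {
    stop_located("anova_screen needs >= 2 samples per place x bw_group cell")
  }
  res <- lapply(rownames(rel), function(tx) {
    y <- rel[tx, ]
    if (transform == "arcsine") y <- asin(sqrt(pmin(pmax(y / 100, 0), 1)))
    if (stats::var(y) == 0) {
      return(data.frame(taxon = tx, p_sp = NA_real_, p_bw = NA_real_,
                        p_int = NA_real_, tukey_sp = NA_character_,
                        p_bw_JC = NA_real_, p_bw_JM = NA_real_,
                        p_bw_CC = NA_real_, note = "constant abundance",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::aov(y ~ place * bw)
    pv <- summary(fit)[[1L]][["Pr(>F)"]]
    tk <- stats::TukeyHSD(fit, which = "place")$place
    lev <- levels(place)
    sig <- matrix(FALSE, length(lev), length(lev),
                  dimnames = list(lev, lev))
    for (cmp in rownames(tk)) {
      pair <- strsplit(cmp, "-", fixed = TRUE)[[1L]]
      s <- tk[cmp, "p adj"] < config$alpha
      sig[pair[1L], pair[2L]] <- s
      sig[pair[2L], pair[1L]] <- s
    }
    mean_by_place <- tapply(y, place, mean)
    lets <- letters_from_significance(sig, mean_by_place)
    within <- vapply(PLACES, function(pl) {
      if (!(pl %in% levels(place))) return(NA_real_)
      idx <- place == pl
      if (length(unique(bw[idx])) < 2L || stats::var(y[idx]) == 0) {
        return(NA_real_)
      }
      stats::anova(stats::lm(y[idx] ~ bw[idx]))[["Pr(>F)"]][1L]
    }, numeric(1L))
    data.frame(taxon = tx, p_sp = pv[1L], p_bw = pv[2L], p_int = pv[3L],
               tukey_sp = paste(paste0(names(lets), ":", lets),
                                collapse = ","),
               p_bw_JC = within[["JC"]], p_bw_JM = within[["JM"]],
               p_bw_CC = within[["CC"]], note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  for (eff in c("sp", "bw", "int")) {
    raw <- out[[paste0("p_", eff)]]
    adj <- rep(NA_real_, length(raw))
    ok <- !is.na(raw)
    adj[ok] <- stats::p.adjust(raw[ok], method = "BH")
    out[[paste0("fdr_", eff)]] <- adj
    out[[paste0("class_", eff)]] <- significance_class(adj, config)
  }
  out
}

significance_class <- function(p, config) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < config$alpha, "significant",
                ifelse(p >= config$trend_band[1L] & p <= config$trend_band[2L],
                       "trend", "ns")))
}

#' Unique and shared feature accounting across groups
#'
#' A feature belongs to a group if it has at least one count in any sample
#' of the group. Region counts follow by set algebra (the numbers behind
#' a Venn diagram); the core is the intersection over all groups.
#'
#' @param counts integer matrix, features x samples.
#' @param meta sample metadata.
#' @param by grouping column, `"place"` or `"bw_group"`.
#' @return list with `group_totals`, `unique_counts`, `core_count` and
#'   `region_counts` (named by the group combination, `+`-separated).
#' @export
venn_unique_shared <- function(counts, meta, by = c("place", "bw_group")) {
  by <- match.arg(by)
  assert_sample_frame(meta)
  m <- meta[match(colnames(counts), meta$sample_id), ]
  groups <- as.character(unique(m[[by]]))
  groups <- groups[order(match(groups, c(PLACES, BW_GROUPS)))]
  present <- vapply(groups, function(g) {
    rowSums(counts[, m[[by]] == g, drop = FALSE]) >= 1
  }, logical(nrow(counts)))
  membership <- apply(present, 1L, function(v) {
    paste(groups[v], collapse = "+")
  })
  membership <- membership[nzchar(membership)]
  region_counts <- table(membership)
  totals <- colSums(present)
  uniq <- vapply(groups, function(g) {
    sum(present[, g] & rowSums(present) == 1L)
  }, numeric(1L))
  core <- sum(rowSums(present) == length(groups))
  list(group_totals = totals,
       unique_counts = uniq,
       core_count = core,
       region_counts = as.list(region_counts))
}
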
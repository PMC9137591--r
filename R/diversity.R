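#' Drop features below a minimum total count
#'
#' Features whose total across all samples is below `min_total` are
#' removed; the boundary is inclusive (a feature with exactly `min_total`
#' reads is retained). Row order is otherwise preserved.
#'
#' @param counts integer matrix, features x samples.
#' @param min_total minimum summed count (>= 0).
#' @return the filtered count matrix.
#' @export
filter_low_abundance <- function(counts, min_total = 10) {
  assert_count_matrix(counts)
  stopifnot(min_total >= 0)
  counts[rowSums(counts) >= min_total, , drop = FALSE]
}

#' Rarefy every sample to a common depth
#'
#' Each retained sample is subsampled once, without replacement, to
#' exactly `depth` reads. Samples with fewer than `depth` total reads are
#' dropped with a warning naming them; if no sample reaches the depth the
#' call fails.
#'
#' @param counts integer matrix, features x samples.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; the draw is deterministic under it.
#' @return integer matrix over the retained samples, column sums all equal
#'   to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 10000, seed = 1L) {
  assert_count_matrix(counts)
  stopifnot(depth >= 1)
  totals <- colSums(counts)
  keep <- totals >= depth
  if (!any(keep)) {
    stop_located("no sample reaches the rarefaction depth %d (max total %d)",
                 depth, max(totals))
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(counts)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  kept <- counts[, keep, drop = FALSE]
  # depth feasibility is validated above; vegan's count heuristics warn
  # spuriously on simulated tables without singletons
  out <- withr::with_seed(as.integer(seed),
                          t(suppressWarnings(vegan::rrarefy(t(kept),
                                                            sample = depth))))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(kept)
  out
}

#' Per-sample alpha diversity
#'
#' Computes observed features, bias-corrected Chao1
#' (`S_obs + F1(F1-1) / (2(F2+1))` with F1/F2 the singleton/doubleton
#' counts), Shannon entropy in the configured log base, the Gini-Simpson
#' index `1 - sum p^2`, and — when a rooted tree is supplied — Faith's PD,
#' the total branch length of the minimal rooted subtree spanning the
#' sample's observed leaves. Empty samples get `NA` indices with a
#' warning.
#'
#' @param counts integer matrix, features x samples.
#' @param tree optional rooted `phylo` covering all features.
#' @param log_base Shannon logarithm base (default 2).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL, log_base = 2) {
  assert_count_matrix(counts)
  x <- t(counts)                          # samples x features
  nonempty <- rowSums(x) > 0
  if (any(!nonempty)) {
    warning(sprintf("empty sample(s), indices reported as NA: %s",
                    paste(rownames(x)[!nonempty], collapse = ", ")),
            call. = FALSE)
  }
  res <- data.frame(sample_id = rownames(x),
                    observed = NA_real_, chao1 = NA_real_,
                    shannon = NA_real_, simpson = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(nonempty)) {
    xs <- x[nonempty, , drop = FALSE]
    res$observed[nonempty] <- vegan::specnumber(xs)
    est <- suppressWarnings(vegan::estimateR(xs))  # chao SE NaN when F1 = F2 = 0
    res$chao1[nonempty] <- est["S.chao1", ]
    res$shannon[nonempty] <-
      vegan::diversity(xs, index = "shannon") / log(log_base)
    res$simpson[nonempty] <- vegan::diversity(xs, index = "simpson")
  }
  if (!is.null(tree)) {
    if (!ape::is.rooted(tree)) {
      stop_located("Faith's PD requires a rooted tree")
    }
    missing_tips <- setdiff(rownames(counts), tree$tip.label)
    if (length(missing_tips)) {
      stop_located("tree is missing %d feature(s), e.g. %s",
                   length(missing_tips), missing_tips[1L])
    }
    res$faith_pd <- NA_real_
    if (any(nonempty)) {
      pd <- picante::pd(x[nonempty, , drop = FALSE], tree,
                        include.root = TRUE)
      res$faith_pd[nonempty] <- pd$PD
    }
  }
  res
}

#' Monte Carlo rarefaction curve
#'
#' Mean observed feature count per sample across `reps` random subsamples
#' at each requested depth. Depths exceeding a sample's total are skipped
#' for that sample.
#'
#' @param counts integer matrix, features x samples.
#' @param depths ascending integer depths.
#' @param reps subsamples averaged per depth.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `depth`, `mean_observed`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 10, seed = 1L) {
  assert_count_matrix(counts)
  stopifnot(all(diff(depths) > 0), all(depths >= 1), reps >= 1)
  totals <- colSums(counts)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (s in seq_len(ncol(counts))) {
      for (d in depths) {
        if (d > totals[s]) next
        obs <- numeric(reps)
        xs <- t(counts[, s, drop = FALSE])
        for (r in seq_len(reps)) {
          sub <- suppressWarnings(vegan::rrarefy(xs, sample = d))
          obs[r] <- sum(sub > 0)
        }
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = colnames(counts)[s], depth = d,
                     mean_observed = mean(obs), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
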
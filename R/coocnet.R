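# Co-occurrence networks for five-sample groups: prevalence filtering,
# exact small-n Spearman, |rho|-threshold edge calling, and Monte Carlo
# significance of per-genus connection counts and of components.

#' Exact Spearman correlation for very small samples
#'
#' At the group sizes these networks run on (typically n = 5) asymptotic
#' Spearman p-values are meaningless, so the permutation null is
#' enumerated exactly. For n <= 8 all n! orderings of one vector are
#' enumerated; ties are handled with average ranks and by permuting the
#' observed values themselves, so the null conditions on the observed tie
#' pattern. For larger untied samples the exact null distribution of
#' `S = sum d^2` is used (dynamic programming, n <= 12); beyond that, or
#' with ties, a t-approximation is the fallback.
#'
#' One-sided p is `P(rho_null >= rho_obs)`; two-sided is
#' `P(|rho_null| >= |rho_obs|)`. Enumeration includes the identity
#' permutation, so p is never 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `rho`, `one_sided_p`, `two_sided_p`, `n` and
#'   `method` (`"enumeration"`, `"exact_s"`, or `"t_approx"`). A constant
#'   vector yields `rho = NA` and `method = "undefined"`.
#' @export
exact_spearman <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(rho = NA_real_, one_sided_p = NA_real_,
                two_sided_p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  eps <- 1e-10
  if (n <= 8L) {
    P <- all_perms(n)
    Y <- matrix(ry[P], nrow(P), n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_all <- as.vector(Y %*% rxc) / denom   # Y rows sum against centred rx
    return(list(rho = rho,
                one_sided_p = mean(rho_all >= rho - eps),
                two_sided_p = mean(abs(rho_all) >= abs(rho) - eps),
                n = n, method = "enumeration"))
  }
  tied <- anyDuplicated(rx) || anyDuplicated(ry)
  if (!tied && n <= 12L) {
    cnt <- spearman_s_distribution(n)
    total <- sum(cnt)
    s_vals <- seq_along(cnt) - 1
    rho_vals <- 1 - 6 * s_vals / (n^3 - n)
    return(list(rho = rho,
                one_sided_p = sum(cnt[rho_vals >= rho - eps]) / total,
                two_sided_p = sum(cnt[abs(rho_vals) >= abs(rho) - eps]) / total,
                n = n, method = "exact_s"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  one <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  list(rho = rho, one_sided_p = one,
       two_sided_p = min(1, 2 * min(one, 1 - one)),
       n = n, method = "t_approx")
}

#' Genera passing a per-group prevalence filter
#'
#' A genus enters a group's network only if its relative abundance is
#' non-zero in at least `min_present` of the group's samples (the 4-of-5
#' rule by default).
#'
#' @param rel matrix, genera x samples.
#' @param meta sample metadata.
#' @param place,bw_group the group selector.
#' @param min_present minimum samples with non-zero abundance.
#' @return character vector of retained genus ids.
#' @export
prevalence_filter_group <- function(rel, meta, place, bw_group,
                                    min_present = 4) {
  idx <- group_sample_ids(meta, place, bw_group)
  if (length(idx) < min_present) {
    stop_located("group %s/%s has %d sample(s), fewer than min_present = %d",
                 place, bw_group, length(idx), min_present)
  }
  sub <- rel[, idx, drop = FALSE]
  rownames(sub)[rowSums(sub > 0) >= min_present]
}

group_sample_ids <- function(meta, place, bw_group) {
  assert_sample_frame(meta)
  meta$sample_id[as.character(meta$place) == place &
                 as.character(meta$bw_group) == bw_group]
}

# Column-standardised rank matrix: Pearson correlation of its columns is
# the Spearman correlation of the raw columns. Constant columns are left
# as zero so they produce rho = 0 (no edges) rather than NaN.
rank_z <- function(X) {
  R <- apply(X, 2L, rank)
  ctr <- sweep(R, 2L, colMeans(R))
  ss <- sqrt(colSums(ctr^2))
  ss[ss == 0] <- Inf
  sweep(ctr, 2L, ss, "/")
}

adjacency_from_rho <- function(R, rho_min, allow_negative) {
  A <- if (allow_negative) abs(R) >= rho_min - 1e-12 else R >= rho_min - 1e-12
  diag(A) <- FALSE
  A
}

#' Build a within-group co-occurrence network
#'
#' Applies the prevalence filter, computes all pairwise Spearman
#' correlations across the group's samples, and calls an edge wherever
#' `rho >= cooc_edge_rho_min` (or `rho <= -threshold` when negative edges
#' are allowed; the sign is recorded). Each edge carries its exact
#' enumeration p-value, which at n = 5 is descriptive — only |rho| = 1
#' reaches two-sided p < 0.05 — so inference is deferred to the Monte
#' Carlo degree and component tests.
#'
#' @param rel matrix, genera x samples (relative abundance).
#' @param meta sample metadata.
#' @param place,bw_group the group analysed.
#' @param config a [gutcooc_config()].
#' @return a `group_network`: nodes, edge table (genus_a, genus_b, rho,
#'   sign, exact_p), per-node degree, components, and the filtered
#'   samples-by-genera matrix used (for the Monte Carlo tests).
#' @export
build_group_network <- function(rel, meta, place, bw_group,
                                config = gutcooc_config()) {
  genera <- prevalence_filter_group(rel, meta, place, bw_group,
                                    config$cooc_prevalence_min)
  if (length(genera) < 2L) {
    stop_located("fewer than 2 genera pass the prevalence filter in %s/%s",
                 place, bw_group)
  }
  idx <- group_sample_ids(meta, place, bw_group)
  X <- t(rel[genera, idx, drop = FALSE])      # samples x genera
  R <- stats::cor(X, method = "spearman")
  A <- adjacency_from_rho(R, config$cooc_edge_rho_min,
                          config$cooc_allow_negative)
  pairs <- which(A & upper.tri(A), arr.ind = TRUE)
  edges <- if (nrow(pairs)) {
    data.frame(
      genus_a = genera[pairs[, 1L]],
      genus_b = genera[pairs[, 2L]],
      rho = R[pairs],
      sign = ifelse(R[pairs] >= 0, "positive", "negative"),
      exact_p = vapply(seq_len(nrow(pairs)), function(k) {
        exact_spearman(X[, pairs[k, 1L]], X[, pairs[k, 2L]])$two_sided_p
      }, numeric(1L)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(genus_a = character(0), genus_b = character(0),
               rho = numeric(0), sign = character(0), exact_p = numeric(0))
  }
  degree <- stats::setNames(colSums(A), genera)
  comp_id <- uf_components(length(genera),
                           if (nrow(pairs)) unname(pairs) else matrix(0L, 0L, 2L))
  comps <- list()
  for (cid in unique(comp_id)) {
    members <- which(comp_id == cid)
    if (length(members) < 2L) next
    n_edges <- sum(A[members, members]) / 2L
    if (n_edges == 0) next
    comps[[length(comps) + 1L]] <- list(nodes = genera[members],
                                        n_edges = as.integer(n_edges))
  }
  structure(list(place = place, bw_group = bw_group, nodes = genera,
                 samples = idx, edges = edges, degree = degree,
                 components = comps, rho = R, data = X,
                 rho_min = config$cooc_edge_rho_min,
                 allow_negative = config$cooc_allow_negative),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat(sprintf("co-occurrence network %s/%s: %d genera, %d edge(s), %d component(s)\n",
              x$place, x$bw_group, length(x$nodes), nrow(x$edges),
              length(x$components)))
  invisible(x)
}

# Shared Monte Carlo null loop. Permutes each genus's rank vector across
# the group's samples independently (marginals preserved, all cross-genus
# association destroyed), rebuilds the thresholded network, and collects
# per-genus degrees and the maximum per-component edge count.
cooc_null_stats <- function(X, rho_min, allow_negative, B, seed,
                            want_degrees = TRUE, want_max_comp = TRUE) {
  n <- nrow(X); m <- ncol(X)
  Z <- rank_z(X)
  deg_ge <- NULL
  obs <- NULL
  degs <- if (want_degrees) matrix(0L, B, m) else NULL
  maxc <- if (want_max_comp) integer(B) else NULL
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      Zp <- vapply(seq_len(m), function(j) Z[sample.int(n), j], numeric(n))
      R <- crossprod(Zp)
      A <- adjacency_from_rho(R, rho_min, allow_negative)
      if (want_degrees) degs[b, ] <- colSums(A)
      if (want_max_comp) maxc[b] <- max_component_edges(A)
    }
  })
  list(degrees = degs, max_comp_edges = maxc)
}

#' Monte Carlo significance of per-genus connection counts
#'
#' The null model permutes each genus's abundances across the group's
#' samples independently, preserving every marginal while destroying all
#' co-occurrence, and rebuilds the network per replicate. For genus g,
#' `p = (#{null degree of g >= observed degree} + 1) / (B + 1)`; a genus
#' with no observed connections has p = 1 by construction.
#'
#' @param network a [build_group_network()] result (or `cross_network`).
#' @param B null replicates (>= 100).
#' @param seed integer seed.
#' @return named numeric vector of per-genus empirical p-values.
#' @export
mc_degree_significance <- function(network, B = 1000, seed = 1L) {
  stopifnot(B >= 100)
  if (inherits(network, "cross_network")) {
    return(mc_cross_degree(network, B, seed))
  }
  stopifnot(inherits(network, "group_network"))
  nul <- cooc_null_stats(network$data, network$rho_min,
                         network$allow_negative, B, seed,
                         want_degrees = TRUE, want_max_comp = FALSE)
  obs <- network$degree
  cnt <- colSums(nul$degrees >= matrix(obs, B, length(obs), byrow = TRUE))
  stats::setNames((cnt + 1) / (B + 1), names(obs))
}

#' Monte Carlo significance of network components
#'
#' Each observed component is scored by its number of internal edges; the
#' null reference is the maximum component edge count of the rebuilt
#' network per replicate (same permutation null as
#' [mc_degree_significance()]). Comparing every component against the
#' null maximum makes the test family-wise valid across the components of
#' one network. `p = (#{null max >= observed} + 1) / (B + 1)`.
#'
#' @param network a [build_group_network()] result.
#' @param B null replicates (>= 100).
#' @param seed integer seed.
#' @return data.frame with one row per component: its size, edge count
#'   and Monte Carlo p.
#' @export
component_significance <- function(network, B = 1000, seed = 1L) {
  stopifnot(inherits(network, "group_network"), B >= 100)
  if (!length(network$components)) {
    return(data.frame(component = integer(0), n_nodes = integer(0),
                      n_edges = integer(0), p_value = numeric(0),
                      nodes = character(0)))
  }
  nul <- cooc_null_stats(network$data, network$rho_min,
                         network$allow_negative, B, seed,
                         want_degrees = FALSE, want_max_comp = TRUE)
  obs <- vapply(network$components, `[[`, integer(1L), "n_edges")
  p <- vapply(obs, function(o) (sum(nul$max_comp_edges >= o) + 1) / (B + 1),
              numeric(1L))
  data.frame(component = seq_along(obs),
             n_nodes = vapply(network$components, function(cpt)
               length(cpt$nodes), integer(1L)),
             n_edges = obs,
             p_value = p,
             nodes = vapply(network$components, function(cpt)
               paste(cpt$nodes, collapse = ","), character(1L)),
             stringsAsFactors = FALSE)
}

#' Bipartite co-occurrence between two compartments of the same birds
#'
#' For one BW group, aligns the two compartments' samples by bird,
#' applies the prevalence filter per compartment, and correlates every
#' (from-genus, to-genus) pair across the matched birds. Edges use the
#' same |rho| threshold; only cross-compartment edges exist. The per
#' from-genus out-degree is tested by the same Monte Carlo null
#' (permuting the from-compartment genus vectors across birds).
#'
#' @param rel matrix, genera x samples.
#' @param meta sample metadata.
#' @param bw_group BW group analysed.
#' @param config a [gutcooc_config()].
#' @param from,to compartment labels (default jejunum chymus to jejunum
#'   mucosa).
#' @return a `cross_network` with nodes per side, the bipartite edge
#'   table and per-from-genus out-degrees.
#' @export
cross_compartment_network <- function(rel, meta, bw_group,
                                      config = gutcooc_config(),
                                      from = "JC", to = "JM") {
  assert_sample_frame(meta)
  mf <- meta[as.character(meta$place) == from &
             as.character(meta$bw_group) == bw_group, ]
  mt <- meta[as.character(meta$place) == to &
             as.character(meta$bw_group) == bw_group, ]
  if (!setequal(mf$bird_id, mt$bird_id) || !nrow(mf)) {
    stop_located("compartments %s and %s do not cover the same birds in %s",
                 from, to, bw_group)
  }
  mf <- mf[order(mf$bird_id), ]
  mt <- mt[match(mf$bird_id, mt$bird_id), ]
  gf <- prevalence_filter_group(rel, meta, from, bw_group,
                                config$cooc_prevalence_min)
  gt <- prevalence_filter_group(rel, meta, to, bw_group,
                                config$cooc_prevalence_min)
  if (!length(gf) || !length(gt)) {
    stop_located("a compartment has no genera passing the prevalence filter")
  }
  Xf <- t(rel[gf, mf$sample_id, drop = FALSE])   # birds x from-genera
  Xt <- t(rel[gt, mt$sample_id, drop = FALSE])
  R <- stats::cor(Xf, Xt, method = "spearman")
  R[is.na(R)] <- 0
  hit <- if (config$cooc_allow_negative) abs(R) >= config$cooc_edge_rho_min - 1e-12
         else R >= config$cooc_edge_rho_min - 1e-12
  pairs <- which(hit, arr.ind = TRUE)
  edges <- if (nrow(pairs)) {
    data.frame(
      genus_a = gf[pairs[, 1L]],
      genus_b = gt[pairs[, 2L]],
      rho = R[pairs],
      sign = ifelse(R[pairs] >= 0, "positive", "negative"),
      exact_p = vapply(seq_len(nrow(pairs)), function(k) {
        exact_spearman(Xf[, pairs[k, 1L]], Xt[, pairs[k, 2L]])$two_sided_p
      }, numeric(1L)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(genus_a = character(0), genus_b = character(0),
               rho = numeric(0), sign = character(0), exact_p = numeric(0))
  }
  out_degree <- stats::setNames(rowSums(hit), gf)
  structure(list(bw_group = bw_group, from = from, to = to,
                 from_nodes = gf, to_nodes = gt,
                 birds = mf$bird_id, edges = edges,
                 degree = out_degree,
                 data_from = Xf, data_to = Xt,
                 rho_min = config$cooc_edge_rho_min,
                 allow_negative = config$cooc_allow_negative),
            class = "cross_network")
}

#' @export
print.cross_network <- function(x, ...) {
  cat(sprintf("cross-compartment network %s->%s (%s): %d x %d genera, %d edge(s)\n",
              x$from, x$to, x$bw_group, length(x$from_nodes),
              length(x$to_nodes), nrow(x$edges)))
  invisible(x)
}

mc_cross_degree <- function(network, B, seed) {
  Zf <- rank_z(network$data_from)
  Zt <- rank_z(network$data_to)
  n <- nrow(Zf); m <- ncol(Zf)
  obs <- network$degree
  cnt <- numeric(m)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      Zp <- vapply(seq_len(m), function(j) Zf[sample.int(n), j], numeric(n))
      R <- crossprod(Zp, Zt)
      hit <- if (network$allow_negative) abs(R) >= network$rho_min - 1e-12
             else R >= network$rho_min - 1e-12
      cnt <- cnt + (rowSums(hit) >= obs)
    }
  })
  stats::setNames((cnt + 1) / (B + 1), names(obs))
}
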
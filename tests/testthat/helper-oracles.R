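# Independent oracles and small fixture builders. Everything here is
# deliberately written by a different route than the package code it
# checks (plain recursion, closed forms, exhaustive set enumeration).

# All permutations of v, by plain list recursion (not the package's
# block-construction algorithm).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Exhaustive-enumeration Spearman p-values on average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  rhos <- vapply(oracle_perms(seq_along(y)),
                 function(p) stats::cor(rx, rank(y[p])), numeric(1L))
  list(rho = rho,
       one_sided_p = mean(rhos >= rho - 1e-10),
       two_sided_p = mean(abs(rhos) >= abs(rho) - 1e-10))
}

# Faith's PD by brute force: an edge belongs to the spanning subtree iff
# its child subtree contains an observed leaf.
oracle_faith_pd <- function(tree, observed_tips) {
  obs <- match(observed_tips, tree$tip.label)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    tips <- if (child <= length(tree$tip.label)) child else {
      cl <- ape::extract.clade(tree, child)
      match(cl$tip.label, tree$tip.label)
    }
    if (any(tips %in% obs)) total <- total + tree$edge.length[e]
  }
  total
}

# Benjamini-Hochberg by the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Tukey HSD p-value from the studentized range distribution.
oracle_tukey_p <- function(mean_i, mean_j, mse, n_per_group, k, df) {
  q <- abs(mean_i - mean_j) / sqrt(mse / n_per_group)
  stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
}

# Balanced 2-group x 3-place x n-bird metadata.
make_meta <- function(n_birds = 5, places = c("JC", "JM", "CC"),
                      seed = 1) {
  withr::with_seed(seed, {
    birds <- data.frame(
      bird_id = c(sprintf("LBW_b%d", seq_len(n_birds)),
                  sprintf("HBW_b%d", seq_len(n_birds))),
      bw_group = rep(c("LBW", "HBW"), each = n_birds),
      body_weight_g = c(stats::runif(n_birds, 2100, 2460),
                        stats::runif(n_birds, 2930, 3300)))
    do.call(rbind, lapply(places, function(pl) {
      data.frame(sample_id = paste(pl, birds$bird_id, sep = "_"),
                 bird_id = birds$bird_id, place = pl,
                 bw_group = birds$bw_group,
                 body_weight_g = birds$body_weight_g)
    }))
  })
}

# Random genus x sample relative-abundance matrix (percent).
random_rel <- function(n_genera, meta, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rlnorm(n_genera * nrow(meta)), n_genera,
                dimnames = list(sprintf("g%03d", seq_len(n_genera)),
                                meta$sample_id))
    sweep(x, 2L, colSums(x), "/") * 100
  })
}
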
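#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on non-negative
#' abundance profiles (columns). A pair of all-zero samples gets distance
#' 0 with a warning. Bray-Curtis is a semimetric: the triangle inequality
#' can fail, which is why it is ordinated with PCoA rather than embedded
#' directly.
#'
#' @param rel non-negative matrix, features x samples (counts or relative
#'   abundances).
#' @return symmetric matrix of dissimilarities with zero diagonal.
#' @export
bray_curtis <- function(rel) {
  if (any(rel < 0)) stop_located("Bray-Curtis requires non-negative input")
  x <- t(rel)
  # vegdist warns about empty rows; the resulting NaNs are handled below
  D <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(!is.finite(D))) {
    warning("all-zero sample pair(s); their Bray-Curtis distance set to 0",
            call. = FALSE)
    D[!is.finite(D)] <- 0
  }
  D
}

#' Chi-square distance between sample profiles
#'
#' The correspondence-analysis chi-square distance between row profiles of
#' the grand-total-normalised table:
#' `d(i, j) = sqrt( sum_k (1/c_k) (p_ik / r_i - p_jk / r_j)^2 )`, where
#' `c_k` are column (feature) masses. Rare features carry more weight than
#' under Bray-Curtis. Features never observed are dropped with a warning
#' (their column mass is zero).
#'
#' @param rel non-negative matrix, features x samples, positive sample
#'   sums.
#' @return symmetric matrix of distances.
#' @export
chi_square_distance <- function(rel) {
  if (any(rel < 0)) stop_located("chi-square distance requires non-negative input")
  if (any(colSums(rel) <= 0)) stop_located("every sample needs a positive total")
  zero <- rowSums(rel) <= 0
  if (any(zero)) {
    warning(sprintf("dropping %d feature(s) with zero total from the chi-square distance",
                    sum(zero)), call. = FALSE)
    rel <- rel[!zero, , drop = FALSE]
  }
  as.matrix(vegan::vegdist(t(rel), method = "chisq"))
}

#' Principal coordinate analysis
#'
#' Gower-centres `-D^2 / 2` and eigen-decomposes it. Axes are ordered by
#' eigenvalue; negative eigenvalues (possible for semimetric input such as
#' Bray-Curtis) are reported, not dropped or corrected.
#'
#' @param D symmetric distance matrix (n >= 3 samples).
#' @return list with `coordinates` (samples x axes, positive-eigenvalue
#'   axes) and `eigenvalues` (all, including negatives).
#' @export
pcoa_ordination <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop_located("PCoA needs at least 3 samples")
  if (any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0)) {
    stop_located("PCoA input must be symmetric with a zero diagonal")
  }
  fit <- ape::pcoa(stats::as.dist(D))
  coords <- fit$vectors
  rownames(coords) <- rownames(D)
  list(coordinates = coords, eigenvalues = fit$values$Eigenvalues)
}

new_ordination_test <- function(method, statistic, p_value, n_permutations,
                                seed) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed),
            class = "ordination_test")
}

#' @export
print.ordination_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

check_grouping <- function(D, labels) {
  labels <- factor(labels)
  if (length(labels) != nrow(as.matrix(D))) {
    stop_located("labels length does not match the distance matrix")
  }
  if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
    stop_located("need >= 2 groups with >= 2 samples each")
  }
  labels
}

#' Distance-based PERMANOVA (one factor)
#'
#' Pseudo-F from within/between sums of squared distances with a free
#' label-permutation null; `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`,
#' so p can never be 0 and its floor is `1/(n_perm + 1)`.
#'
#' @param D symmetric distance matrix.
#' @param labels group labels (>= 2 groups, each n >= 2).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an `ordination_test` with the pseudo-F statistic.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1L) {
  labels <- check_grouping(D, labels)
  df <- data.frame(g = labels)
  fit <- withr::with_seed(as.integer(seed),
                          vegan::adonis2(stats::as.dist(as.matrix(D)) ~ g,
                                         data = df, permutations = n_perm))
  new_ordination_test("PERMANOVA", fit$F[1L], fit$`Pr(>F)`[1L],
                      n_perm, as.integer(seed))
}

#' ANOSIM on a distance matrix
#'
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`; permutation p as in [permanova()].
#'
#' @inheritParams permanova
#' @return an `ordination_test` with the ANOSIM R statistic.
#' @export
anosim_test <- function(D, labels, n_perm = 999, seed = 1L) {
  labels <- check_grouping(D, labels)
  fit <- withr::with_seed(as.integer(seed),
                          vegan::anosim(stats::as.dist(as.matrix(D)), labels,
                                        permutations = n_perm))
  new_ordination_test("ANOSIM", unname(fit$statistic), fit$signif,
                      n_perm, as.integer(seed))
}

#' Canonical correspondence analysis with a permutation test
#'
#' Correspondence analysis of the chi-square-standardised abundance table
#' with sample scores constrained by weighted least squares on the design
#' matrix. Returns the constrained axes, the fraction of total inertia
#' they explain, and a permutation test of the constrained pseudo-F.
#'
#' @param rel non-negative matrix, features x samples.
#' @param constraint data.frame (or vector) of explanatory variables, one
#'   row per sample; no constant columns, full column rank.
#' @param n_perm permutations for the pseudo-F test.
#' @param seed integer seed.
#' @return list with `site_scores`, `eigenvalues` (constrained),
#'   `n_constrained_axes`, `constrained_inertia_fraction` and `test` (an
#'   `ordination_test`).
#' @export
cca_constrained <- function(rel, constraint, n_perm = 999, seed = 1L) {
  comm <- t(rel)
  env <- as.data.frame(constraint)
  if (nrow(env) != nrow(comm)) {
    stop_located("constraint rows must match the number of samples")
  }
  mm <- stats::model.matrix(~ ., data = env)
  if (any(apply(mm[, -1L, drop = FALSE], 2L, function(v) length(unique(v)) == 1L))) {
    stop_located("constraint contains a constant column")
  }
  if (qr(mm)$rank < ncol(mm)) {
    stop_located("constraint design matrix is rank-deficient")
  }
  fit <- vegan::cca(comm ~ ., data = env)
  tst <- withr::with_seed(as.integer(seed),
                          stats::anova(fit, permutations = n_perm))
  list(site_scores = vegan::scores(fit, display = "sites",
                                   choices = seq_len(fit$CCA$rank)),
       eigenvalues = fit$CCA$eig,
       n_constrained_axes = fit$CCA$rank,
       constrained_inertia_fraction = fit$CCA$tot.chi / fit$tot.chi,
       test = new_ordination_test("CCA pseudo-F", tst$F[1L],
                                  tst$`Pr(>F)`[1L], n_perm,
                                  as.integer(seed)))
}
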
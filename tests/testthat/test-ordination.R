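test_that("Bray-Curtis matches hand-evaluated cases", {
  rel <- cbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0))
  rownames(rel) <- c("f1", "f2", "f3")
  D <- bray_curtis(rel)
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 0)
  disjoint <- cbind(a = c(1, 0), b = c(0, 2))
  rownames(disjoint) <- c("f1", "f2")
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  withzero <- cbind(a = c(0, 0), b = c(0, 0))
  rownames(withzero) <- c("f1", "f2")
  expect_warning(Dz <- bray_curtis(withzero), "all-zero")
  expect_equal(Dz["a", "b"], 0)
  expect_error(bray_curtis(-rel), "non-negative")
})

test_that("chi-square distance follows the correspondence-analysis formula", {
  rel <- cbind(a = c(1, 0), b = c(0, 1))
  rownames(rel) <- c("f1", "f2")
  expect_equal(chi_square_distance(rel)["a", "b"], 2)

  same <- cbind(a = c(2, 4), b = c(1, 2))   # identical profiles
  rownames(same) <- c("f1", "f2")
  expect_equal(chi_square_distance(same)["a", "b"], 0)

  # global rescaling cancels in the grand-total normalisation
  rel3 <- random_rel(6, make_meta(2, places = "JC"), seed = 5)
  expect_equal(chi_square_distance(rel3), chi_square_distance(rel3 * 7))

  # direct formula evaluation on a random table
  P <- rel3 / sum(rel3)
  r <- colSums(P); cmass <- rowSums(P)   # samples are columns here
  d12 <- sqrt(sum((P[, 1] / r[1] - P[, 2] / r[2])^2 / cmass))
  expect_equal(chi_square_distance(rel3)[1, 2], unname(d12))
})

test_that("PCoA reproduces exact Euclidean configurations", {
  pts <- cbind(x = c(0, 3, 3, 0), y = c(0, 0, 4, 4))
  rownames(pts) <- paste0("s", 1:4)
  D <- as.matrix(stats::dist(pts))
  fit <- pcoa_ordination(D)
  expect_equal(sum(fit$eigenvalues),
               sum(diag(-0.5 * (diag(4) - 1 / 4) %*% D^2 %*%
                          (diag(4) - 1 / 4))),
               tolerance = 1e-8)
  proc <- vegan::procrustes(pts, fit$coordinates[, 1:2], symmetric = FALSE)
  expect_lt(sum(proc$residuals^2), 1e-8)

  # 1-D configuration -> a single non-trivial axis
  line <- as.matrix(stats::dist(cbind(c(0, 1, 2, 5))))
  dimnames(line) <- list(paste0("s", 1:4), paste0("s", 1:4))
  fit1 <- pcoa_ordination(line)
  expect_identical(sum(abs(fit1$eigenvalues) > 1e-8), 1L)
  expect_error(pcoa_ordination(D[1:2, 1:2]), "3 samples")
})

test_that("PERMANOVA reaches the permutation floor on separated clusters", {
  withr::with_seed(1, {
    x <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(10, 100), 5))
  })
  rownames(x) <- paste0("s", 1:10)
  D <- as.matrix(stats::dist(x))
  g <- rep(c("a", "b"), each = 5)
  fit <- permanova(D, g, n_perm = 999, seed = 1)
  # with balanced 5+5 labels ~0.8% of label permutations reproduce the
  # observed partition and tie with the observed pseudo-F, so the
  # attainable floor sits near 0.009, never below 1/(n_perm + 1)
  expect_gte(fit$p_value, 0.001)
  expect_lte(fit$p_value, 0.02)

  # statistic invariant to consistent sample reordering
  o <- withr::with_seed(2, sample(10))
  fit2 <- permanova(D[o, o], g[o], n_perm = 99, seed = 1)
  expect_equal(fit2$statistic, fit$statistic)
  expect_error(permanova(D, rep("a", 10)), "2 groups")
})

test_that("PERMANOVA null p-values are uniform on the permutation grid", {
  ps <- vapply(1:300, function(i) {
    withr::with_seed(3000 + i, {
      x <- matrix(rnorm(8 * 4), 8)
      D <- as.matrix(stats::dist(x))
      dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
      permanova(D, rep(c("a", "b"), each = 4), n_perm = 99,
                seed = 7000 + i)$p_value
    })
  }, numeric(1L))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(all(ps >= 1 / 100))
})

test_that("ANOSIM attains R = 1 under complete separation and is centred under the null", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  })
  D <- as.matrix(stats::dist(x))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  fit <- anosim_test(D, rep(c("a", "b"), each = 5), n_perm = 199, seed = 1)
  expect_equal(fit$statistic, 1)
  expect_lt(fit$p_value, 0.05)

  rs <- vapply(1:300, function(i) {
    withr::with_seed(5000 + i, {
      x <- matrix(rnorm(8 * 4), 8)
      D <- as.matrix(stats::dist(x))
      dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
      anosim_test(D, sample(rep(c("a", "b"), each = 4)), n_perm = 19,
                  seed = i)$statistic
    })
  }, numeric(1L))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("CCA constrained axes, invariances and null calibration behave", {
  meta <- make_meta(5, places = "JC")
  rel <- random_rel(20, meta, seed = 6)
  bw <- data.frame(bw = factor(meta$bw_group))
  fit <- cca_constrained(rel, bw, n_perm = 199, seed = 1)
  expect_identical(fit$n_constrained_axes, 1L)  # single binary constraint
  expect_true(fit$constrained_inertia_fraction > 0 &&
                fit$constrained_inertia_fraction < 1)

  # duplicating every feature leaves the constrained inertia fraction alone
  rel2 <- rbind(rel, rel)
  rownames(rel2) <- sprintf("f%03d", seq_len(nrow(rel2)))
  fit2 <- cca_constrained(rel2, bw, n_perm = 99, seed = 1)
  expect_equal(fit2$constrained_inertia_fraction,
               fit$constrained_inertia_fraction, tolerance = 1e-10)

  expect_error(cca_constrained(rel, data.frame(k = rep(1, 10))), "constant")
  expect_error(
    cca_constrained(rel, data.frame(a = meta$body_weight_g,
                                    b = meta$body_weight_g * 2)),
    "rank-deficient")

  # permuted labels: non-significant in the vast majority of null runs
  hits <- vapply(1:100, function(i) {
    lab <- withr::with_seed(800 + i, sample(meta$bw_group))
    cca_constrained(rel, data.frame(bw = factor(lab)), n_perm = 99,
                    seed = 900 + i)$test$p_value <= 0.05
  }, logical(1L))
  expect_lte(mean(hits), 0.10)
})
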
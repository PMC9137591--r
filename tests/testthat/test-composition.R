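test_that("rank aggregation is additive and conserves column sums", {
  counts <- matrix(c(3L, 4L, 5L, 1L, 2L, 3L), 3, 2,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  tax <- data.frame(feature_id = c("f1", "f2"),
                    kingdom = "Bacteria", phylum = c("Firmicutes", "Firmicutes"),
                    class = "c", order = "o", family = "f",
                    genus = c("g1", "g2"), species = "s")
  ph <- aggregate_to_rank(counts, tax, "phylum")
  expect_equal(ph["Firmicutes", "s1"], 7)
  expect_equal(ph["Unclassified", "s1"], 5)   # f3 unmapped but retained
  expect_equal(colSums(ph), colSums(counts))

  none <- aggregate_to_rank(counts, tax[0, ], "genus")
  expect_identical(rownames(none), "Unclassified")
})

test_that("relative abundance columns sum to 100", {
  counts <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  rel <- to_relative(counts)
  expect_equal(rel[, 1], c(a = 25, b = 75))
  m <- random_rel(10, make_meta(3, places = "JC"), seed = 2)
  expect_equal(unname(colSums(to_relative(m))), rep(100, ncol(m)))
  zero <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_error(to_relative(zero), "zero-sum")
})

test_that("group-mean margins are the means of their cells", {
  meta <- make_meta()
  rel <- random_rel(4, meta, seed = 3)
  gmt <- group_mean_table(rel, meta)
  for (tx in rownames(rel)) {
    for (gr in c("LBW", "HBW")) {
      expect_equal(gmt$mean_bw[tx, gr], mean(gmt$cells[tx, , gr]))
      idx <- meta$bw_group == gr & meta$place == "JM"
      expect_equal(gmt$cells[tx, "JM", gr],
                   mean(rel[tx, meta$sample_id[idx]]))
    }
    for (pl in c("JC", "JM", "CC")) {
      expect_equal(gmt$mean_sp[tx, pl], mean(gmt$cells[tx, pl, ]))
    }
  }
  # constant taxon -> all cells and margins equal that constant
  relc <- rel; relc[1, ] <- 7
  gmc <- group_mean_table(relc, meta)
  expect_true(all(gmc$cells[1, , ] == 7))
  expect_true(all(gmc$mean_bw[1, ] == 7))

  # unbalanced designs are refused
  expect_error(group_mean_table(rel[, -1], meta[-1, ]), "unbalanced")
})

test_that("B/F ratio is computed per sample and averaged per group", {
  meta <- make_meta(2, places = "JC")
  rel <- matrix(c(20, 40, 40,  0, 20, 80,  10, 10, 80,  10, 40, 50), 3, 4,
                dimnames = list(c("Bacteroidetes", "Firmicutes", "Other"),
                                meta$sample_id))
  bf <- bf_ratio(rel, meta)
  expect_equal(bf$per_sample$bf_ratio, c(0.5, 0, 1, 0.25))
  # mean of ratios differs from ratio of means (Jensen gap)
  lbw <- bf$group_means$bf_ratio[bf$group_means$bw_group == "LBW"]
  expect_equal(lbw, mean(c(0.5, 0)))
  ratio_of_means <- mean(rel[1, 1:2]) / mean(rel[2, 1:2])
  expect_false(isTRUE(all.equal(lbw, ratio_of_means)))

  relz <- rel; relz["Firmicutes", 1] <- 0
  expect_warning(bfz <- bf_ratio(relz, meta), "zero Firmicutes")
  expect_true(is.na(bfz$per_sample$bf_ratio[1]))
})

test_that("two-way ANOVA F statistics match the sums-of-squares oracle", {
  meta <- make_meta()
  rel <- random_rel(3, meta, seed = 4)
  scr <- anova_screen(rel, meta)
  for (tx in rownames(rel)) {
    y <- rel[tx, meta$sample_id]
    A <- factor(meta$place); B <- factor(meta$bw_group)
    n <- 5; a <- nlevels(A); b <- nlevels(B)
    cell <- tapply(y, list(A, B), mean)
    gm <- mean(y)
    ssa <- n * b * sum((rowMeans(cell) - gm)^2)
    ssb <- n * a * sum((colMeans(cell) - gm)^2)
    ssab <- n * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") + gm)^2)
    sse <- sum((y - cell[cbind(A, B)])^2)
    dfe <- a * b * (n - 1)
    f <- c(ssa / (a - 1), ssb / (b - 1), ssab / ((a - 1) * (b - 1))) /
      (sse / dfe)
    p <- stats::pf(f, c(a - 1, b - 1, (a - 1) * (b - 1)), dfe,
                   lower.tail = FALSE)
    row <- scr[scr$taxon == tx, ]
    expect_equal(c(row$p_sp, row$p_bw, row$p_int), unname(p),
                 tolerance = 1e-10)
  }
  expect_true(all(scr$fdr_sp >= scr$p_sp - 1e-12))
})

test_that("constant taxa are excluded from the FDR families with a note", {
  meta <- make_meta()
  rel <- random_rel(3, meta, seed = 5)
  rel[2, ] <- 1
  scr <- anova_screen(rel, meta)
  expect_true(is.na(scr$p_sp[2]))
  expect_match(scr$note[2], "constant")
  expect_equal(scr$fdr_sp[-2], stats::p.adjust(scr$p_sp[-2], "BH"))
})

test_that("a large planted place effect is recovered by the FDR screen", {
  meta <- make_meta()
  hits <- vapply(1:100, function(i) {
    rel <- random_rel(10, meta, seed = 6000 + i)
    shift <- ifelse(meta$place == "JC", 30, 0)
    rel[1, ] <- rel[1, ] + shift[match(colnames(rel), meta$sample_id)]
    scr <- anova_screen(rel, meta)
    scr$fdr_sp[1] < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.90)
})

test_that("under the null, raw screen p-values are uniform and FDR positives rare", {
  meta <- make_meta()
  res <- lapply(1:40, function(i) {
    rel <- 100 * prop.table(matrix(
      withr::with_seed(7000 + i, stats::rlnorm(25 * 30)), 25,
      dimnames = list(sprintf("g%02d", 1:25), meta$sample_id)), 2)
    anova_screen(rel, meta)
  })
  raw <- unlist(lapply(res, `[[`, "p_bw"))
  expect_gt(suppressWarnings(stats::ks.test(raw, "punif"))$p.value, 0.01)
  fdr_pos <- mean(unlist(lapply(res, `[[`, "fdr_bw")) < 0.05)
  expect_lte(fdr_pos, 0.05)
})

test_that("Tukey letters agree with the studentized-range formula", {
  meta <- make_meta()
  rel <- random_rel(1, meta, seed = 8)
  shift <- ifelse(meta$place == "JC", 40, 0)
  rel[1, ] <- rel[1, ] + shift[match(colnames(rel), meta$sample_id)]
  scr <- anova_screen(rel, meta)
  lets <- scr$tukey_sp[1]
  # JC is shifted far away: it must carry a letter the others do not
  parsed <- strsplit(strsplit(lets, ",")[[1]], ":")
  lab <- stats::setNames(vapply(parsed, `[`, "", 2),
                         vapply(parsed, `[`, "", 1))
  expect_false(grepl(lab[["JC"]], lab[["JM"]], fixed = TRUE))
  expect_identical(lab[["JM"]], lab[["CC"]])

  # p-value oracle on the place factor of a hand-built one-way layout
  y <- rel[1, meta$sample_id]
  fit <- stats::aov(y ~ place * bw, data = data.frame(
    place = factor(meta$place), bw = factor(meta$bw_group)))
  tk <- stats::TukeyHSD(fit, which = "place")$place
  mse <- sum(fit$residuals^2) / fit$df.residual
  means <- tapply(y, meta$place, mean)
  for (cmp in rownames(tk)) {
    pair <- strsplit(cmp, "-")[[1]]
    expect_equal(tk[cmp, "p adj"],
                 unname(oracle_tukey_p(means[pair[1]], means[pair[2]], mse,
                                       n_per_group = 10, k = 3,
                                       df = fit$df.residual)),
                 tolerance = 1e-8)
  }
})

test_that("unique/shared accounting matches exhaustive set enumeration", {
  meta <- make_meta(1)   # 1 bird per group: 6 samples over 3 places
  inc <- rbind(c(1, 0, 0, 0, 0, 0),
               c(1, 1, 0, 0, 0, 0),
               c(0, 0, 1, 1, 0, 0),
               c(1, 0, 1, 0, 1, 0),
               c(0, 0, 0, 0, 0, 1),
               c(1, 1, 1, 1, 1, 1))
  ord <- order(match(meta$place, c("JC", "JM", "CC")))
  counts <- matrix(0L, 6, 6,
                   dimnames = list(sprintf("otu%d", 1:6), meta$sample_id))
  counts[, meta$sample_id[ord]] <- as.integer(inc)
  v <- venn_unique_shared(counts, meta, by = "place")

  sets <- lapply(c("JC", "JM", "CC"), function(pl) {
    rownames(counts)[rowSums(counts[, meta$sample_id[meta$place == pl],
                                    drop = FALSE]) > 0]
  })
  names(sets) <- c("JC", "JM", "CC")
  expect_equal(unname(v$group_totals[c("JC", "JM", "CC")]),
               unname(lengths(sets)))
  expect_equal(v$core_count,
               length(Reduce(intersect, sets)))
  expect_equal(unname(v$unique_counts["JC"]),
               length(setdiff(sets$JC, union(sets$JM, sets$CC))))
  # inclusion-exclusion: region counts add up to the union
  expect_equal(sum(unlist(v$region_counts)),
               length(Reduce(union, sets)))
})
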
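# Crafted 5-sample group over a balanced 10-bird metadata frame.
cooc_meta <- function() make_meta(5)

test_that("the prevalence filter applies the 4-of-5 rule at the boundary", {
  meta <- cooc_meta()
  rel <- random_rel(3, meta, seed = 1)
  jc_lbw <- meta$sample_id[meta$place == "JC" & meta$bw_group == "LBW"]
  rel["g001", jc_lbw[1:2]] <- 0    # 3 of 5 -> out
  rel["g002", jc_lbw[1]] <- 0      # 4 of 5 -> in
  kept <- prevalence_filter_group(rel, meta, "JC", "LBW", min_present = 4)
  expect_false("g001" %in% kept)
  expect_true(all(c("g002", "g003") %in% kept))
  expect_identical(sort(prevalence_filter_group(rel, meta, "JC", "LBW", 0)),
                   sort(rownames(rel)))
  expect_error(prevalence_filter_group(rel, meta, "JC", "LBW", 6), "fewer")
})

test_that("exact_spearman matches closed-form and antisymmetry expectations", {
  es <- exact_spearman(1:5, c(10, 20, 30, 40, 50))
  expect_equal(es$rho, 1)
  expect_equal(es$one_sided_p, 1 / 120)
  expect_equal(es$two_sided_p, 2 / 120)

  x <- c(2.3, 1.1, 5.2, 0.4, 3.3); y <- c(4, 2, 6, 1, 9)
  a <- exact_spearman(x, y)
  b <- exact_spearman(rev(x), rev(y))          # reordering both: unchanged
  expect_equal(a, b)
  r <- exact_spearman(-x, y)                   # negation flips rho only
  expect_equal(r$rho, -a$rho)
  expect_equal(r$two_sided_p, a$two_sided_p)

  expect_identical(exact_spearman(rep(1, 5), 1:5)$method, "undefined")
})

test_that("the exact S-distribution route agrees with full enumeration", {
  for (i in 1:25) {
    n <- withr::with_seed(i, sample(7:8, 1))
    x <- withr::with_seed(100 + i, stats::rnorm(n))
    y <- withr::with_seed(200 + i, stats::rnorm(n))
    enum <- exact_spearman(x, y)               # n <= 8: enumeration
    expect_identical(enum$method, "enumeration")
    dp <- gutcooc:::spearman_s_distribution(n)
    rho_vals <- 1 - 6 * (seq_along(dp) - 1) / (n^3 - n)
    two <- sum(dp[abs(rho_vals) >= abs(enum$rho) - 1e-10]) / sum(dp)
    one <- sum(dp[rho_vals >= enum$rho - 1e-10]) / sum(dp)
    expect_equal(two, enum$two_sided_p, tolerance = 1e-12)
    expect_equal(one, enum$one_sided_p, tolerance = 1e-12)
  }
})

test_that("edge calling, components and thresholds follow the rules", {
  meta <- cooc_meta()
  rel <- random_rel(3, meta, seed = 2)
  jm_lbw <- meta$sample_id[meta$place == "JM" & meta$bw_group == "LBW"]
  rel["g001", jm_lbw] <- 1:5
  rel["g002", jm_lbw] <- c(2, 4, 6, 8, 10)        # rho(g1,g2) = 1
  rel["g003", jm_lbw] <- c(1, 2, 3, 5, 4)         # rho = 0.9 with both
  cfg <- gutcooc_config()
  net <- build_group_network(rel, meta, "JM", "LBW", cfg)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(length(net$components), 1L)
  expect_identical(sort(net$components[[1]]$nodes), c("g001", "g002", "g003"))
  expect_equal(unname(net$degree), c(2, 2, 2))
  expect_equal(net$edges$exact_p[net$edges$genus_a == "g001" &
                                   net$edges$genus_b == "g002"], 2 / 120)

  cfg_hi <- gutcooc_config(cooc_edge_rho_min = 1.01)
  net_hi <- build_group_network(rel, meta, "JM", "LBW", cfg_hi)
  expect_identical(nrow(net_hi$edges), 0L)
  expect_identical(length(net_hi$components), 0L)

  expect_error(build_group_network(rel * 0 + c(1, 0, 0), meta, "JM", "LBW",
                                   cfg), "fewer than 2")
})

test_that("negative edges are called and signed when allowed", {
  meta <- cooc_meta()
  rel <- random_rel(2, meta, seed = 3)
  jc_lbw <- meta$sample_id[meta$place == "JC" & meta$bw_group == "LBW"]
  rel["g001", jc_lbw] <- 1:5
  rel["g002", jc_lbw] <- 5:1
  net <- build_group_network(rel, meta, "JC", "LBW")
  expect_identical(net$edges$sign, "negative")
  net_pos <- build_group_network(rel, meta, "JC", "LBW",
                                 gutcooc_config(cooc_allow_negative = FALSE))
  expect_identical(nrow(net_pos$edges), 0L)
})

test_that("network construction is equivariant to consistent sample relabeling", {
  meta <- cooc_meta()
  rel <- random_rel(8, meta, seed = 4)
  net <- build_group_network(rel, meta, "CC", "HBW")
  perm <- withr::with_seed(5, sample(ncol(rel)))
  net2 <- build_group_network(rel[, perm], meta, "CC", "HBW")
  key <- function(n) n$edges[order(n$edges$genus_a, n$edges$genus_b),
                             c("genus_a", "genus_b", "rho")]
  expect_equal(key(net), key(net2), ignore_attr = TRUE)
})

test_that("Monte Carlo degree p-values are deterministic, floored and 1 for isolates", {
  meta <- cooc_meta()
  rel <- random_rel(10, meta, seed = 6)
  net <- build_group_network(rel, meta, "JM", "HBW")
  p <- mc_degree_significance(net, B = 199, seed = 9)
  expect_identical(p, mc_degree_significance(net, B = 199, seed = 9))
  expect_true(all(p >= 1 / 200 & p <= 1))
  expect_true(all(p[net$degree == 0] == 1))
})

test_that("a genus wired to five perfect partners has a tiny degree p", {
  meta <- cooc_meta()
  hits <- vapply(1:20, function(i) {
    rel <- random_rel(12, meta, seed = 300 + i)
    grp <- meta$sample_id[meta$place == "JM" & meta$bw_group == "LBW"]
    base <- withr::with_seed(400 + i, stats::rnorm(5))
    for (k in 1:6) rel[k, grp] <- exp(base * k)  # six mutually perfect genera
    net <- build_group_network(rel, meta, "JM", "LBW")
    p <- mc_degree_significance(net, B = 999, seed = 500 + i)
    p["g001"] <= 0.01
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("component significance flags a planted block and not a saturated null", {
  meta <- cooc_meta()
  d <- synthetic_design(
    places = "JM", n_genera = 30,
    planted_blocks = list(list(places = "JM",
                               genera = sprintf("g%03d", 1:7),
                               loading = 2)),
    seed = 77)
  sim <- simulate_counts(d)
  rel <- to_relative(sim$counts)
  net <- build_group_network(rel, sim$meta, "JM", "LBW")
  comp <- component_significance(net, B = 999, seed = 1)
  planted_comp <- vapply(net$components, function(cpt)
    all(sprintf("g%03d", 1:7) %in% cpt$nodes), logical(1L))
  expect_true(any(planted_comp))
  expect_lte(comp$p_value[which(planted_comp)], 0.05)

  # without planted structure the max-null construction keeps the
  # family-wise rate of small component p-values low
  small_p <- vapply(1:30, function(i) {
    reln <- random_rel(20, meta, seed = 900 + i)
    netn <- build_group_network(reln, meta, "JC", "LBW")
    cn <- component_significance(netn, B = 199, seed = 950 + i)
    nrow(cn) > 0 && min(cn$p_value) <= 0.05
  }, logical(1L))
  expect_lte(mean(small_p), 0.2)
})

test_that("cross-compartment networks align birds and detect identity edges", {
  meta <- cooc_meta()
  rel <- random_rel(6, meta, seed = 9)
  jc <- meta$sample_id[meta$place == "JC" & meta$bw_group == "LBW"]
  jm <- meta$sample_id[meta$place == "JM" & meta$bw_group == "LBW"]
  birds_jc <- meta$bird_id[match(jc, meta$sample_id)]
  birds_jm <- meta$bird_id[match(jm, meta$sample_id)]
  vals <- withr::with_seed(10, stats::runif(5))
  rel["g001", jc] <- vals[match(birds_jc, sort(birds_jc))]
  rel["g002", jm] <- vals[match(birds_jm, sort(birds_jm))]
  net <- cross_compartment_network(rel, meta, "LBW")
  hit <- net$edges[net$edges$genus_a == "g001" & net$edges$genus_b == "g002", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$rho, 1)
  expect_gte(net$degree[["g001"]], 1)
  p <- mc_degree_significance(net, B = 199, seed = 1)
  expect_identical(names(p), net$from_nodes)

  bad <- meta
  bad$bird_id[bad$sample_id == jm[1]] <- "other_bird"
  expect_error(cross_compartment_network(rel, bad, "LBW"), "same birds")
})

test_that("shuffling the bird alignment destroys planted cross edges", {
  block <- sprintf("g%03d", 1:7)
  aligned <- integer(10); shuffled <- integer(10)
  for (i in 1:10) {
    d <- synthetic_design(
      places = c("JC", "JM"), n_genera = 20,
      planted_blocks = list(list(places = c("JC", "JM"), genera = block,
                                 loading = 3)),
      seed = 600 + i)
    sim <- simulate_counts(d)
    rel <- to_relative(sim$counts)
    net <- cross_compartment_network(rel, sim$meta, "LBW")
    pl_edges <- sum(net$edges$genus_a %in% block & net$edges$genus_b %in% block)
    aligned[i] <- pl_edges
    # break the alignment by permuting JM birds
    meta2 <- sim$meta
    jm <- meta2$place == "JM" & meta2$bw_group == "LBW"
    meta2$bird_id[jm] <- withr::with_seed(700 + i,
                                          sample(meta2$bird_id[jm]))
    net2 <- cross_compartment_network(rel, meta2, "LBW")
    shuffled[i] <- sum(net2$edges$genus_a %in% block &
                         net2$edges$genus_b %in% block)
  }
  expect_gt(mean(aligned), mean(shuffled))
  expect_gte(mean(aligned), 10)   # 7x7 block pairs, most near rho = 1
})
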
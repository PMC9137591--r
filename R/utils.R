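# Internal helpers shared across modules.

.gutcooc_cache <- new.env(parent = emptyenv())

#' Derive a deterministic child seed from a master seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a short character tag, so that stages are reproducible in
#' isolation and adding a stage never shifts the random stream of another.
#'
#' @param seed integer master seed.
#' @param tag character stage tag.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  s <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(tag)) {
    s <- (s * 31 + ch) %% 2147483647
  }
  as.integer(s) + 1L
}

stop_located <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count_matrix <- function(counts, what = "count table") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_located("%s must be a numeric matrix (features x samples)", what)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_located("%s must carry feature rownames and sample colnames", what)
  }
  if (anyDuplicated(rownames(counts))) {
    stop_located("duplicate feature id: %s",
                 rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (anyDuplicated(colnames(counts))) {
    stop_located("duplicate sample id: %s",
                 colnames(counts)[duplicated(colnames(counts))][1L])
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1L, ]
    stop_located("%s cell [%s, %s] is not a non-negative integer", what,
                 rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  invisible(counts)
}

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species")
PLACES <- c("JC", "JM", "CC")
BW_GROUPS <- c("LBW", "HBW")

assert_sample_frame <- function(meta) {
  need <- c("sample_id", "bird_id", "place", "bw_group", "body_weight_g")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop_located("metadata is missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop_located("duplicate sample_id: %s",
                 meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  bad <- setdiff(unique(meta$place), PLACES)
  if (length(bad)) {
    stop_located("unknown sampling place label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(PLACES, collapse = ", "))
  }
  bad <- setdiff(unique(meta$bw_group), BW_GROUPS)
  if (length(bad)) {
    stop_located("unknown bw_group label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "), paste(BW_GROUPS, collapse = ", "))
  }
  if (any(!is.finite(meta$body_weight_g)) || any(meta$body_weight_g <= 0)) {
    stop_located("body_weight_g must be a positive number for every sample")
  }
  if (anyDuplicated(meta[, c("bird_id", "place")])) {
    stop_located("(bird_id, place) pairs must be unique in the metadata")
  }
  invisible(meta)
}

#' All permutations of 1..n (memoised)
#'
#' Used by the exact Spearman enumeration; feasible for n <= 8 (8! = 40320).
#' @keywords internal
all_perms <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  key <- paste0("perms", n)
  if (!is.null(.gutcooc_cache[[key]])) return(.gutcooc_cache[[key]])
  pm <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- all_perms_uncached(n)
    sub
  }
  .gutcooc_cache[[key]] <- pm
  pm
}

all_perms_uncached <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- if (n - 1L <= 8L && !is.null(.gutcooc_cache[[paste0("perms", n - 1L)]])) {
    .gutcooc_cache[[paste0("perms", n - 1L)]]
  } else {
    all_perms_uncached(n - 1L)
  }
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(
      if (pos > 1L) sub[, seq_len(pos - 1L), drop = FALSE],
      n,
      if (pos < n) sub[, pos:(n - 1L), drop = FALSE]
    )
    out[r + seq_len(nrow(sub)), ] <- as.integer(block)
    r <- r + nrow(sub)
  }
  out
}

#' Exact null distribution of Spearman's S = sum (i - pi(i))^2 for untied ranks
#'
#' Counts permutations of 1..n attaining each value of S by dynamic
#' programming over subsets of ranks. Exact for n <= 12 (memory-bound).
#'
#' @return numeric vector `cnt` with `cnt[s + 1] = #permutations with S = s`.
#' @keywords internal
spearman_s_distribution <- function(n) {
  stopifnot(n >= 2L, n <= 12L)
  key <- paste0("sdist", n)
  if (!is.null(.gutcooc_cache[[key]])) return(.gutcooc_cache[[key]])
  smax <- sum((seq_len(n) - rev(seq_len(n)))^2)
  nmask <- bitwShiftL(1L, n)
  popcnt <- integer(nmask)
  for (m in seq_len(nmask - 1L)) {
    popcnt[m + 1L] <- popcnt[bitwAnd(m, m - 1L) + 1L] + 1L
  }
  f <- vector("list", nmask)
  f[[1L]] <- c(1, numeric(smax))        # empty assignment, S = 0
  for (m in seq_len(nmask - 1L)) {
    i <- popcnt[m + 1L]                 # position being filled
    acc <- numeric(smax + 1L)
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0L) next
      prev <- f[[bitwXor(m, bit) + 1L]]
      d2 <- (i - j)^2
      if (d2 == 0) {
        acc <- acc + prev
      } else {
        idx <- seq_len(smax + 1L - d2)
        acc[idx + d2] <- acc[idx + d2] + prev[idx]
      }
    }
    f[[m + 1L]] <- acc
    # free the previous popcount layer lazily; fine at n <= 12
  }
  out <- f[[nmask]]
  .gutcooc_cache[[key]] <- out
  out
}

# Connected components of an undirected graph on nodes 1..n given an edge
# list (2-column integer matrix). Plain union-find; nodes are few.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

# Maximum number of edges in any connected component; the null statistic of
# the component significance test. adjacency = logical matrix with diagonal
# TRUE/FALSE irrelevant (upper triangle used).
max_component_edges <- function(adj) {
  n <- nrow(adj)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  comp <- uf_components(n, idx)
  ce <- table(comp[idx[, 1L]])
  as.integer(max(ce))
}

# Compact letter display from a logical "significantly different" matrix.
# Groups joined by a letter iff no pair inside the letter differs; letters
# are the maximal cliques of the non-significance graph, ordered by the
# group means so that 'a' sits on the largest mean.
letters_from_significance <- function(signif_mat, means) {
  k <- nrow(signif_mat)
  if (k == 1L) return(stats::setNames("a", rownames(signif_mat)))
  nonsig <- !signif_mat
  diag(nonsig) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  best <- vapply(cl, function(v) max(means[v]), numeric(1L))
  cl <- cl[order(-best)]
  lab <- rep("", k)
  for (i in seq_along(cl)) {
    lab[cl[[i]]] <- paste0(lab[cl[[i]]], letters[i])
  }
  stats::setNames(lab, rownames(signif_mat))
}
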
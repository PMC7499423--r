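# Independent brute-force oracles, kept free of the implementation paths
# they check.

# KS statistic by scanning every pooled breakpoint of the two ECDFs.
brute_ks <- function(x, y) {
  ts <- sort(unique(c(x, y)))
  max(vapply(ts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Exhaustive top-k neighbors of point i by pairwise euclidean distance,
# ties broken by index.
brute_knn <- function(coords, i, k) {
  d <- sqrt(colSums((t(coords) - coords[i, ])^2))
  cand <- setdiff(seq_len(nrow(coords)), i)
  cand[order(d[cand], cand)][seq_len(k)]
}

# Per-type marker scores recomputed gene by gene, type by type.
brute_marker_top <- function(means, n_top, pseudocount) {
  types <- rownames(means)
  out <- list()
  for (t in types) {
    score <- vapply(colnames(means), function(g) {
      log10(means[t, g] + pseudocount) -
        log10(max(means[setdiff(types, t), g]) + pseudocount)
    }, numeric(1))
    ord <- order(-score, colnames(means))
    out[[t]] <- colnames(means)[ord][seq_len(n_top)]
  }
  out
}

# Fano factors recomputed per gene with a plain loop.
brute_fano <- function(vals) {
  vapply(seq_len(nrow(vals)), function(i) {
    x <- vals[i, ]
    if (mean(x) == 0) 0 else var(x) / mean(x)
  }, numeric(1))
}

# CPM objective by edge-by-edge summation.
brute_cpm_objective <- function(g, membership, gamma) {
  w <- 0
  for (e in seq_len(nrow(g$edges))) {
    if (membership[g$edges$from[e]] == membership[g$edges$to[e]]) {
      w <- w + g$edges$weight[e]
    }
  }
  for (c in unique(membership)) {
    nc <- sum(g$nodes$size[membership == c])
    w <- w - gamma * nc * (nc - 1) / 2
  }
  w
}

# --- exact constrained optimum by exhaustive enumeration ------------------
# All label-respecting partitions of a graph whose atlas nodes are one per
# label (nodes 1..n_labels): new node j takes a label community 1..L or a
# novel community, novel ids introduced in canonical (increasing) order.

enumerate_constrained_assignments <- function(n_new, n_labels) {
  states <- vector("list", 0)
  rec <- function(prefix, n_novel_used) {
    i <- length(prefix) + 1L
    if (i > n_new) {
      states[[length(states) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in c(seq_len(n_labels), n_labels + seq_len(n_novel_used + 1L))) {
      rec(c(prefix, v), max(n_novel_used, v - n_labels))
    }
  }
  rec(integer(0), 0L)
  do.call(rbind, states)
}

# Objective of many states at once (vectorized over states).
constrained_objectives <- function(g, states) {
  n_labels <- sum(g$nodes$is_atlas)
  n <- nrow(g$nodes)
  full <- cbind(matrix(rep(seq_len(n_labels), each = nrow(states)),
                       nrow(states)), states)
  W <- numeric(nrow(states))
  for (e in seq_len(nrow(g$edges))) {
    same <- full[, g$edges$from[e]] == full[, g$edges$to[e]]
    W <- W + g$edges$weight[e] * same
  }
  s <- g$nodes$size
  sum_sq <- rep(sum(s^2), nrow(states))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      same <- full[, i] == full[, j]
      sum_sq <- sum_sq + 2 * s[i] * s[j] * same
    }
  }
  W - attr(states, "gamma") * (sum_sq - sum(s)) / 2
}

exact_constrained_optimum <- function(g, gamma) {
  n_labels <- sum(g$nodes$is_atlas)
  stopifnot(identical(which(g$nodes$is_atlas), seq_len(n_labels)))
  states <- enumerate_constrained_assignments(sum(!g$nodes$is_atlas), n_labels)
  attr(states, "gamma") <- gamma
  max(constrained_objectives(g, states))
}
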
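# Brute-force oracles, independent of the package's implementation paths.

# all-pairs shortest directed distances by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_path_stats <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  list(char_path_length = if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_,
       global_efficiency = mean(ifelse(is.finite(off), 1 / off, 0)))
}

# betweenness via shortest-path counting with matrix powers: walks of the
# minimal length are exactly the shortest paths
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  pow <- list(diag(n))
  maxd <- max(d[is.finite(d) & d > 0], 0)
  for (L in seq_len(max(maxd, 1))) pow[[L + 1]] <- pow[[L]] %*% a
  npaths <- function(i, j) if (!is.finite(d[i, j])) 0 else pow[[d[i, j] + 1]][i, j]
  b <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v) next
    if (!is.finite(d[s, t])) next
    if (is.finite(d[s, v]) && is.finite(d[v, t]) && d[s, v] + d[v, t] == d[s, t])
      b[v] <- b[v] + npaths(s, v) * npaths(v, t) / npaths(s, t)
  }
  b / ((n - 1) * (n - 2))
}

# Fagiolo clustering by explicit neighbour-pair loops
oracle_clustering <- function(a) {
  n <- nrow(a)
  s <- a + t(a)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dtot <- sum(a[i, ]) + sum(a[, i])
    dbi <- sum(a[i, ] * a[, i])
    den <- 2 * (dtot * (dtot - 1) - 2 * dbi)
    if (den <= 0) next
    tri <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tri <- tri + s[i, j] * s[j, h] * s[h, i]
    }
    out[i] <- tri / den
  }
  out
}

# Reference exemplars of the 13 connected triad classes, in the standard
# triad-census order (021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D,
# 120U, 120C, 210, 300).  Classification = isomorphism against these under
# all 6 node permutations.
triad_exemplars <- local({
  e <- function(...) {
    a <- matrix(0L, 3, 3)
    for (p in list(...)) a[p[1], p[2]] <- 1L
    a
  }
  list(
    e(c(2, 1), c(2, 3)),                                  # 021D
    e(c(1, 2), c(3, 2)),                                  # 021U
    e(c(1, 2), c(2, 3)),                                  # 021C
    e(c(1, 2), c(2, 1), c(3, 2)),                         # 111D
    e(c(1, 2), c(2, 1), c(2, 3)),                         # 111U
    e(c(1, 2), c(3, 2), c(1, 3)),                         # 030T
    e(c(1, 2), c(2, 3), c(3, 1)),                         # 030C
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),                # 201
    e(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),                # 120D
    e(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),                # 120U
    e(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),                # 120C
    e(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),       # 210
    e(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1)) # 300
  )
})

perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

oracle_triad_class <- function(a3) {
  diag(a3) <- 0L
  for (id in 1:13) {
    ex <- triad_exemplars[[id]]
    for (r in 1:6) {
      p <- perms3[r, ]
      if (all(a3[p, p] == ex)) return(id)
    }
  }
  NA_integer_
}

oracle_motif_census <- function(a) {
  n <- nrow(a)
  counts <- integer(13)
  if (n < 3) return(counts)
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    id <- oracle_triad_class(a[trip, trip])
    if (!is.na(id)) counts[id] <- counts[id] + 1L
  }
  counts
}

# naive influence covariate: scan all reference spikes per evaluation time
oracle_influence <- function(ref, times, tau) {
  vapply(times, function(t) {
    s <- ref[ref <= t]
    if (!length(s)) 0 else exp(-(t - max(s)) / tau)
  }, numeric(1))
}

# exact four-state dyad probabilities of the P1 model
p1_dyad_probs <- function(theta, rho, ai, aj, bi, bj) {
  lw <- c(0, theta + ai + bj, theta + aj + bi,
          2 * theta + rho + ai + aj + bi + bj)
  w <- exp(lw - max(lw))
  w / sum(w)
}

# random adjacency matrix helpers
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(rbinom(n * n, 1, p), n, n)
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  dimnames(a) <- list(seq_len(n), seq_len(n))
  a
}

# minimal truth_graph constructor for hand-built coupling layouts
truth_from_edges <- function(n, edges, weights) {
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  structure(list(n_nodes = as.integer(n),
                 edges = cbind(source = as.integer(edges[, 1]),
                               target = as.integer(edges[, 2])),
                 weights = as.numeric(weights)),
            class = "truth_graph")
}
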
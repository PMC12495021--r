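# 3-node directed motif taxonomy -------------------------------------------
#
# A triad's edge configuration is one of 64 codes over the six ordered pairs
# (1,2),(2,1),(1,3),(3,1),(2,3),(3,2); bit b of code = presence of pair b.
# Exactly 13 weakly-connected isomorphism classes exist.  Motif IDs 1..13
# follow the standard triad-census (M-A-N) ordering of the connected
# classes — 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D, 120U,
# 120C, 210, 300 — which sorts by edge count (2,2,2,3,3,3,3,4,4,4,4,5,6);
# the fully bidirectional triangle is ID 13.  The 64 -> {0..13} lookup is
# built once per session by exhaustive enumeration and cached.

motif_cache <- new.env(parent = emptyenv())

triad_code_to_adj <- function(code) {
  bits <- as.integer(intToBits(code))[1:6]
  a <- matrix(0L, 3, 3)
  a[cbind(c(1, 2, 1, 3, 2, 3), c(2, 1, 3, 1, 3, 2))] <- bits
  a
}

triad_adj_to_code <- function(a) {
  bits <- a[cbind(c(1, 2, 1, 3, 2, 3), c(2, 1, 3, 1, 3, 2))]
  sum(bits * 2L^(0:5))
}

# canonical representative of a code's isomorphism orbit: minimum code over
# the 6 node permutations
triad_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                     c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))

triad_canonical_code <- function(code) {
  a <- triad_code_to_adj(code)
  min(apply(triad_perms, 1, function(p) triad_adj_to_code(a[p, p])))
}

triad_weakly_connected <- function(a) {
  u <- (a + t(a)) > 0
  # 3 nodes: connected iff at least two of the three undirected pairs linked
  sum(u[upper.tri(u)]) >= 2
}

build_motif_lookup <- function() {
  if (!is.null(motif_cache$lookup)) return(motif_cache$lookup)
  canon <- vapply(0:63, triad_canonical_code, numeric(1))
  connected <- vapply(0:63, function(cd) triad_weakly_connected(triad_code_to_adj(cd)),
                      logical(1))
  classes <- sort(unique(canon[connected]))
  stopifnot(length(classes) == 13L)
  # ID of each class = its slot in the standard 16-class triad census minus
  # the 3 disconnected classes; this sorts classes by edge count
  # (2,2,2,3,3,3,3,4,4,4,4,5,6) with the conventional D/U/C sub-order
  id_of_class <- vapply(classes, function(cd) {
    g <- igraph::graph_from_adjacency_matrix(triad_code_to_adj(cd),
                                             mode = "directed")
    as.integer(which(igraph::triad_census(g) == 1L) - 3L)
  }, integer(1))
  lookup <- integer(64)
  idx <- which(connected)
  lookup[idx] <- id_of_class[match(canon[idx], classes)]
  motif_cache$lookup <- lookup
  lookup
}

#' Classify a 3-node induced subgraph into its structural motif class
#'
#' Returns the motif ID (1-13) of the weakly-connected isomorphism class of
#' a 3-node directed graph, or `NA` when the triad is not weakly connected.
#' IDs follow the standard triad-census ordering (see
#' [motif_census()]); the fully bidirectional triangle is ID 13.
#'
#' @param a 3x3 binary adjacency matrix (no self-loops).
#' @return integer motif ID in 1..13, or `NA`.
#' @export
triad_class <- function(a) {
  a <- as.matrix(a)
  if (!all(dim(a) == c(3, 3))) stop("triad must have exactly 3 nodes", call. = FALSE)
  diag(a) <- 0L
  lookup <- build_motif_lookup()
  id <- lookup[triad_adj_to_code(a) + 1L]
  if (id == 0L) NA_integer_ else id
}

#' Census of 3-node structural motifs
#'
#' Counts the weakly-connected node triples of a binary directed graph by
#' motif class.  Structural counting classifies each triple by its induced
#' subgraph (each connected triple is counted exactly once); functional
#' counting (Milo-style) additionally counts every connected spanning
#' 3-node subgraph contained in the induced subgraph.  Triples are found by
#' enumerating, for every node, the unordered pairs of its (weak)
#' neighbours — every connected triple has such a centre node.
#'
#' @param a 0/1 adjacency matrix (n >= 3).
#' @param counting `"structural"` (default) or `"functional"`.
#' @return integer vector of length 13, named `ID-1` ... `ID-13`.
#' @export
motif_census <- function(a, counting = c("structural", "functional")) {
  counting <- match.arg(counting)
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  trip <- connected_triples(a)
  counts <- integer(13)
  if (nrow(trip)) {
    codes <- triple_codes(a, trip)
    if (counting == "structural") {
      lookup <- build_motif_lookup()
      ids <- lookup[codes + 1L]
      counts <- tabulate(ids, nbins = 13)
    } else {
      fl <- build_functional_table()
      counts <- as.integer(colSums(fl[codes + 1L, , drop = FALSE]))
    }
  }
  stats::setNames(counts, paste0("ID-", 1:13))
}

# all weakly-connected unordered triples, via centre-node enumeration
connected_triples <- function(a) {
  u <- (a + t(a)) > 0
  nb <- lapply(seq_len(nrow(a)), function(v) which(u[v, ]))
  out <- vector("list", nrow(a))
  for (v in seq_len(nrow(a))) {
    nv <- nb[[v]]
    if (length(nv) >= 2) {
      pr <- utils::combn(nv, 2)
      out[[v]] <- cbind(pmin(v, pr[1, ], pr[2, ]),
                        apply(rbind(v, pr), 2, function(x) sort(x)[2]),
                        pmax(v, pr[1, ], pr[2, ]))
    }
  }
  trip <- do.call(rbind, out)
  if (is.null(trip)) return(matrix(integer(0), 0, 3))
  unique(trip)
}

triple_codes <- function(a, trip) {
  i <- trip[, 1]; j <- trip[, 2]; k <- trip[, 3]
  a[cbind(i, j)] + 2L * a[cbind(j, i)] + 4L * a[cbind(i, k)] +
    8L * a[cbind(k, i)] + 16L * a[cbind(j, k)] + 32L * a[cbind(k, j)]
}

# functional counting table: row (code+1) holds, per motif class, how many
# connected spanning sub-triads the configuration contains
build_functional_table <- function() {
  if (!is.null(motif_cache$functional)) return(motif_cache$functional)
  lookup <- build_motif_lookup()
  tab <- matrix(0L, 64, 13)
  for (code in 0:63) {
    bits <- which(as.integer(intToBits(code))[1:6] == 1L)
    if (!length(bits)) next
    for (sub in seq_len(2^length(bits)) - 1L) {
      keep <- bits[as.logical(intToBits(sub)[seq_along(bits)])]
      subcode <- sum(2L^(keep - 1L))
      id <- lookup[subcode + 1L]
      if (id > 0L) tab[code + 1L, id] <- tab[code + 1L, id] + 1L
    }
  }
  motif_cache$functional <- tab
  tab
}

#' Degree-preserving graph randomization
#'
#' Rewires a directed graph by `swap_factor * m` attempted edge switches
#' `(a->b, c->d) -> (a->d, c->b)`, rejecting switches that would create a
#' self-loop or duplicate edge.  Every node's in- and out-degree is
#' preserved exactly.  Graphs with fewer than two edges are returned
#' unchanged with a warning.
#'
#' @param a 0/1 adjacency matrix.
#' @param swap_factor attempted switches per edge (default 100).
#' @param seed RNG seed.
#' @return rewired 0/1 adjacency matrix.
#' @export
degree_preserving_randomize <- function(a, swap_factor = 100, seed = 1) {
  a <- check_adjacency(a)
  m <- sum(a)
  if (m < 2) {
    warning("graph has fewer than 2 edges; returned unchanged", call. = FALSE)
    return(a)
  }
  out <- with_seed(seed, edge_swap_cpp(a, as.integer(swap_factor * m)))
  dimnames(out) <- dimnames(a)
  out
}

#' Motif significance against a degree-preserving null ensemble
#'
#' Compares the structural motif census of a graph with the censuses of
#' `n_null` degree-preserving randomizations.  For each motif class the
#' z-score `(count - null mean) / null sd` (undefined when the null sd is
#' zero) and the add-one empirical enrichment p-value
#' `(1 + #{null >= observed}) / (n_null + 1)` are reported; a class is
#' flagged significant when the empirical p falls below `p_threshold`.
#'
#' @param a 0/1 adjacency matrix.
#' @param n_null number of null graphs (default 1000, minimum 100).
#' @param swap_factor attempted switches per edge for each null.
#' @param seed RNG seed.
#' @param p_threshold significance threshold on the empirical p (0.05).
#' @param counting passed to [motif_census()].
#' @return object of class `motif_census_report`: data frame `table` with
#'   columns `motif_id`, `count`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical`, `significant`, plus `n_null` and `seed`.
#' @export
motif_significance <- function(a, n_null = 1000, swap_factor = 100, seed = 1,
                               p_threshold = 0.05,
                               counting = c("structural", "functional")) {
  counting <- match.arg(counting)
  if (n_null < 100) stop("`n_null` must be >= 100", call. = FALSE)
  a <- check_adjacency(a)
  obs <- motif_census(a, counting)
  seeds <- derive_seeds(seed, n_null)
  nulls <- matrix(0L, n_null, 13)
  for (r in seq_len(n_null)) {
    g <- degree_preserving_randomize(a, swap_factor, seeds[r])
    nulls[r, ] <- motif_census(g, counting)
  }
  mu <- colMeans(nulls)
  sdv <- apply(nulls, 2, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  p_emp <- (1 + colSums(nulls >= rep(obs, each = n_null))) / (n_null + 1)
  # the add-one empirical p also settles zero-variance nulls: a count that
  # merely matches a constant null gets p = 1 (not significant, z undefined)
  tab <- data.frame(motif_id = paste0("ID-", 1:13), count = as.integer(obs),
                    null_mean = mu, null_sd = sdv, z = z,
                    p_empirical = p_emp,
                    significant = p_emp < p_threshold,
                    row.names = NULL)
  structure(list(table = tab, n_null = n_null, seed = seed,
                 counting = counting), class = "motif_census_report")
}

#' @export
print.motif_census_report <- function(x, ...) {
  cat("<motif_census_report> ", x$counting, " counting, ", x$n_null,
      " null graphs\n", sep = "")
  print(transform(x$table, null_mean = round(null_mean, 2),
                  null_sd = round(null_sd, 2), z = round(z, 2)))
  invisible(x)
}
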
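# Holland-Leinhardt P1 model ------------------------------------------------
#
# Dyads (unordered node pairs) are independent; the four states of dyad
# {i, j} have log-weights
#   null:    0
#   i -> j:  theta + alpha_i + beta_j
#   j -> i:  theta + alpha_j + beta_i
#   mutual:  2 theta + rho + alpha_i + alpha_j + beta_i + beta_j
# alpha is the per-node expansiveness (propensity to send edges), beta the
# attractiveness (propensity to receive), theta the overall density and rho
# the reciprocity.  Identification: sum(alpha) = sum(beta) = 0.

#' Dyad census of a directed graph
#'
#' @param a 0/1 adjacency matrix (n >= 2).
#' @return list with `mutual`, `asymmetric`, `null`; the three counts sum
#'   to `n (n - 1) / 2`.
#' @export
dyad_census <- function(a) {
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  m <- sum(a * t(a)) / 2
  asym <- sum(a) - 2 * m
  list(mutual = as.integer(m), asymmetric = as.integer(asym),
       null = as.integer(n * (n - 1) / 2 - m - asym))
}

#' Sample a directed graph from the P1 model
#'
#' Draws each dyad independently from its four-state distribution with
#' probabilities proportional to the exponentiated P1 linear predictors.
#'
#' @param theta density parameter.
#' @param rho reciprocity parameter (`-Inf` forbids mutual dyads).
#' @param alpha numeric vector of expansiveness parameters (length n).
#' @param beta_attr numeric vector of attractiveness parameters (length n).
#' @param seed RNG seed.
#' @return 0/1 adjacency matrix.
#' @export
sample_p1_network <- function(theta, rho, alpha, beta_attr, seed = 1) {
  n <- length(alpha)
  if (length(beta_attr) != n) stop("`alpha` and `beta_attr` must match", call. = FALSE)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  if (!all(is.finite(c(theta, alpha, beta_attr))) || is.nan(rho) ||
      identical(rho, Inf))
    stop("non-finite P1 parameters", call. = FALSE)
  a <- matrix(0L, n, n, dimnames = list(seq_len(n), seq_len(n)))
  with_seed(seed, {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lw <- c(0,
              theta + alpha[i] + beta_attr[j],
              theta + alpha[j] + beta_attr[i],
              2 * theta + rho + alpha[i] + alpha[j] + beta_attr[i] + beta_attr[j])
      w <- exp(lw - max(lw[is.finite(lw)]))
      w[!is.finite(lw)] <- 0
      st <- sample.int(4, 1, prob = w)
      if (st == 2L || st == 4L) a[i, j] <- 1L
      if (st == 3L || st == 4L) a[j, i] <- 1L
    }
  })
  a
}

# Dyad state log-weights and probabilities for all pairs (vectorized).
# `allow` is an np x 4 logical matrix of admissible states per dyad (states
# forced on/off by structurally degenerate nodes are removed).
p1_state_probs <- function(theta, rho, alpha, beta, I, J, allow) {
  lw <- cbind(0,
              theta + alpha[I] + beta[J],
              theta + alpha[J] + beta[I],
              2 * theta + rho + alpha[I] + alpha[J] + beta[I] + beta[J])
  lw[!allow] <- -Inf
  mx <- apply(lw, 1, max)
  w <- exp(lw - mx)
  list(lw = lw, P = w / rowSums(w), logZ = log(rowSums(w)) + mx)
}

#' Fit the P1 model by penalized Newton-Raphson
#'
#' Maximum-likelihood fit of the dyad-independent P1 model (including the
#' reciprocity term unless `reciprocity = FALSE`).  The concave dyad
#' log-likelihood is maximized by Newton-Raphson with step halving; a
#' quadratic penalty on `sum(alpha)` and `sum(beta)` selects the centred
#' representative along the likelihood's translation-invariant directions,
#' so at convergence `sum(alpha) = sum(beta) = 0` over the finite
#' estimates and the fitted expected in-/out-degrees match the observed
#' degrees (the MLE moment conditions).
#'
#' Degenerate nodes (out-degree 0 or `n - 1`, in-degree 0 or `n - 1`) have
#' infinite maximum-likelihood coefficients; they are reported as `-Inf` /
#' `+Inf` sentinels, excluded from the centring constraint, and their
#' forced edge states are removed from each affected dyad's state space
#' before fitting, so a node that no train influences does not derail the
#' rest of the fit.  A graph with no mutual dyads likewise yields
#' `rho = -Inf` (noted with a message).
#'
#' @param a 0/1 adjacency matrix (n >= 3).
#' @param tol convergence tolerance on the maximum violation of the moment
#'   conditions (default 1e-6).
#' @param max_iter Newton iteration cap (default 500).
#' @param reciprocity include the mutual-dyad parameter `rho` (default
#'   TRUE).
#' @return object of class `p1_fit` with `theta`, `rho`, `alpha`,
#'   `beta_attr` (named, with infinite sentinels), `converged`, `n_iter`,
#'   `loglik`, `fitted_edge_probs` (marginal edge probabilities) and
#'   `dyads` (the observed dyad census).
#' @export
fit_p1 <- function(a, tol = 1e-6, max_iter = 500, reciprocity = TRUE) {
  a <- check_adjacency(a)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  labs <- rownames(a)
  outd <- rowSums(a); ind <- colSums(a)
  dc <- dyad_census(a)
  alpha_sent <- ifelse(outd == 0, -Inf, ifelse(outd == n - 1, Inf, NA_real_))
  beta_sent <- ifelse(ind == 0, -Inf, ifelse(ind == n - 1, Inf, NA_real_))
  free_a <- is.na(alpha_sent)
  free_b <- is.na(beta_sent)
  rho_sent <- if (reciprocity && dc$mutual == 0) {
    message("no mutual dyads; rho -> -Inf (mutual state excluded)")
    -Inf
  } else NA_real_
  use_rho <- reciprocity && is.na(rho_sent)
  pr <- which(upper.tri(a), arr.ind = TRUE)
  I <- pr[, 1]; J <- pr[, 2]
  np <- length(I)
  # admissible dyad states under structural (infinite-parameter) constraints
  ij_off <- (!free_a[I] & alpha_sent[I] == -Inf) | (!free_b[J] & beta_sent[J] == -Inf)
  ij_on <- (!free_a[I] & alpha_sent[I] == Inf) | (!free_b[J] & beta_sent[J] == Inf)
  ji_off <- (!free_a[J] & alpha_sent[J] == -Inf) | (!free_b[I] & beta_sent[I] == -Inf)
  ji_on <- (!free_a[J] & alpha_sent[J] == Inf) | (!free_b[I] & beta_sent[I] == Inf)
  allow <- matrix(TRUE, np, 4)
  st_ij <- c(FALSE, TRUE, FALSE, TRUE)   # i->j present in state
  st_ji <- c(FALSE, FALSE, TRUE, TRUE)
  for (s in 1:4) {
    if (st_ij[s]) allow[ij_off, s] <- FALSE else allow[ij_on, s] <- FALSE
    if (st_ji[s]) allow[ji_off, s] <- FALSE else allow[ji_on, s] <- FALSE
    if (s == 4 && (!reciprocity || identical(rho_sent, -Inf)))
      allow[, 4] <- FALSE
  }
  obs_state <- 1L + a[cbind(I, J)] + 2L * a[cbind(J, I)]
  # parameter vector: theta, (rho), alpha[free_a], beta[free_b]
  alpha <- numeric(n); beta <- numeric(n)   # zeros in degenerate slots
  theta <- log(max(sum(a), 0.5) / (n * (n - 1)))  # crude start near density
  rho <- 0
  nfa <- sum(free_a); nfb <- sum(free_b)
  ia_idx <- integer(n); ia_idx[free_a] <- (1 + use_rho) + seq_len(nfa)
  ib_idx <- integer(n); ib_idx[free_b] <- (1 + use_rho + nfa) + seq_len(nfb)
  npar <- 1 + use_rho + nfa + nfb
  pen <- 1
  loglik_at <- function() {
    sp <- p1_state_probs(theta, if (use_rho) rho else -Inf, alpha, beta, I, J, allow)
    ll <- sum(sp$lw[cbind(seq_len(np), obs_state)] - sp$logZ)
    sp$loglik <- ll
    sp$penalized <- ll - pen * (sum(alpha[free_a])^2 + sum(beta[free_b])^2)
    sp
  }
  # expected in/out degrees and mutual count under current parameters
  expected_stats <- function(P) {
    pi_ij <- P[, 2] + P[, 4]
    pi_ji <- P[, 3] + P[, 4]
    acc <- function(v, idx) {
      out <- numeric(n)
      s <- rowsum(v, idx)
      out[as.integer(rownames(s))] <- s
      out
    }
    list(out = acc(c(pi_ij, pi_ji), c(I, J)),
         inn = acc(c(pi_ij, pi_ji), c(J, I)),
         mutual = sum(P[, 4]),
         edges = sum(pi_ij) + sum(pi_ji))
  }
  sp <- loglik_at()
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    es <- expected_stats(sp$P)
    # gradient of the (penalized) log-likelihood
    g <- numeric(npar)
    g[1] <- sum(a) - es$edges
    if (use_rho) g[2] <- dc$mutual - es$mutual
    g[ia_idx[free_a]] <- (outd - es$out)[free_a]
    g[ib_idx[free_b]] <- (ind - es$inn)[free_b]
    sa <- sum(alpha[free_a]); sb <- sum(beta[free_b])
    g[ia_idx[free_a]] <- g[ia_idx[free_a]] - 2 * pen * sa
    g[ib_idx[free_b]] <- g[ib_idx[free_b]] - 2 * pen * sb
    # Hessian: -sum of per-dyad covariances of the sufficient statistics;
    # each dyad touches at most 6 parameters, so accumulate 6x6 blocks
    H <- matrix(0, npar, npar)
    for (r in seq_len(np)) {
      i <- I[r]; j <- J[r]
      cols <- c(1L, if (use_rho) 2L,
                if (free_a[i]) ia_idx[i], if (free_a[j]) ia_idx[j],
                if (free_b[i]) ib_idx[i], if (free_b[j]) ib_idx[j])
      k <- length(cols)
      D <- matrix(0, 4, k)
      D[, 1] <- c(0, 1, 1, 2)
      col <- 1L
      if (use_rho) { col <- col + 1L; D[4, col] <- 1 }
      if (free_a[i]) { col <- col + 1L; D[c(2, 4), col] <- 1 }
      if (free_a[j]) { col <- col + 1L; D[c(3, 4), col] <- 1 }
      if (free_b[i]) { col <- col + 1L; D[c(3, 4), col] <- 1 }
      if (free_b[j]) { col <- col + 1L; D[c(2, 4), col] <- 1 }
      p <- sp$P[r, ]
      mu <- colSums(p * D)
      H[cols, cols] <- H[cols, cols] - (crossprod(D, p * D) - outer(mu, mu))
    }
    if (nfa) {
      ja <- ia_idx[free_a]
      H[ja, ja] <- H[ja, ja] - 2 * pen
    }
    if (nfb) {
      jb <- ib_idx[free_b]
      H[jb, jb] <- H[jb, jb] - 2 * pen
    }
    step <- tryCatch(solve(-H + diag(1e-9, npar), g), error = function(e) NULL)
    if (is.null(step)) break
    th0 <- theta; rh0 <- rho; al0 <- alpha; be0 <- beta
    f0 <- sp$penalized
    h <- 0
    repeat {
      s <- step / 2^h
      theta <- th0 + s[1]
      if (use_rho) rho <- rh0 + s[2]
      alpha[free_a] <- al0[free_a] + s[ia_idx[free_a]]
      beta[free_b] <- be0[free_b] + s[ib_idx[free_b]]
      sp <- loglik_at()
      if (sp$penalized >= f0 - 1e-12 || h > 40) break
      h <- h + 1
    }
    es <- expected_stats(sp$P)
    gap <- max(c(abs(outd - es$out)[free_a], abs(ind - es$inn)[free_b],
                 abs(sum(a) - es$edges) / max(1, n),
                 if (use_rho) abs(dc$mutual - es$mutual)))
    if (gap < tol) { converged <- TRUE; break }
    if (max(abs(step / 2^h)) < 1e-12) break
  }
  fp <- matrix(0, n, n, dimnames = list(labs, labs))
  fp[cbind(I, J)] <- sp$P[, 2] + sp$P[, 4]
  fp[cbind(J, I)] <- sp$P[, 3] + sp$P[, 4]
  alpha_out <- ifelse(free_a, alpha, alpha_sent)
  beta_out <- ifelse(free_b, beta, beta_sent)
  structure(list(theta = theta,
                 rho = if (!reciprocity) NA_real_ else if (use_rho) rho else rho_sent,
                 alpha = stats::setNames(alpha_out, labs),
                 beta_attr = stats::setNames(beta_out, labs),
                 converged = converged, n_iter = iter, loglik = sp$loglik,
                 fitted_edge_probs = fp, dyads = dc),
            class = "p1_fit")
}

#' @export
print.p1_fit <- function(x, ...) {
  cat("<p1_fit> theta = ", round(x$theta, 4), ", rho = ", round(x$rho, 4),
      ", ", if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations\n", sep = "")
  fa <- x$alpha[is.finite(x$alpha)]
  fb <- x$beta_attr[is.finite(x$beta_attr)]
  cat("  expansiveness range:  [", round(min(fa), 3), ", ", round(max(fa), 3),
      "]\n  attractiveness range: [", round(min(fb), 3), ", ",
      round(max(fb), 3), "]\n", sep = "")
  invisible(x)
}

#' Rank nodes by expansiveness and attractiveness
#'
#' Returns the top-`k` finite coefficients of each kind, descending, ties
#' broken by node label.
#'
#' @param fit a [fit_p1()] result.
#' @param k number of nodes per list (default 5).
#' @return list with data frames `expansiveness` and `attractiveness`
#'   (`node`, `coefficient`).
#' @export
rank_expansive_attractive <- function(fit, k = 5) {
  stopifnot(inherits(fit, "p1_fit"))
  if (!fit$converged) warning("ranking a non-converged fit", call. = FALSE)
  top <- function(v) {
    v <- v[is.finite(v)]
    if (k > length(v))
      warning("k exceeds the number of finite coefficients", call. = FALSE)
    ord <- order(-v, names(v))
    sel <- utils::head(ord, max(k, 0))
    data.frame(node = names(v)[sel], coefficient = unname(v[sel]),
               row.names = NULL)
  }
  list(expansiveness = top(fit$alpha), attractiveness = top(fit$beta_attr))
}
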
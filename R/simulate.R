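#' Ground-truth directed coupling graph
#'
#' Samples a directed graph with a prescribed density, uniform edge weights
#' (log-hazard-ratio scale) and no self-loops, to serve as the known truth
#' behind [simulate_spike_trains()].
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density fraction of the `n_nodes * (n_nodes - 1)` ordered pairs
#'   that carry an edge; the edge count is `round(density * n * (n - 1))`.
#' @param weight_range length-2 numeric; weights drawn uniformly in this
#'   interval.
#' @param seed RNG seed.
#' @return object of class `truth_graph`: list with `n_nodes`, `edges`
#'   (2-column matrix, `source`/`target` indices), and `weights`.
#' @export
make_ground_truth_graph <- function(n_nodes, density, weight_range = c(0.8, 1.5),
                                    seed = 1) {
  if (n_nodes < 2) stop("`n_nodes` must be >= 2", call. = FALSE)
  if (density < 0 || density > 1)
    stop("`density` must lie in [0, 1]", call. = FALSE)
  stopifnot(length(weight_range) == 2, all(is.finite(weight_range)))
  n_pairs <- n_nodes * (n_nodes - 1L)
  m <- round(density * n_pairs)
  with_seed(seed, {
    idx <- if (m > 0) sample.int(n_pairs, m) else integer(0)
    # enumerate ordered non-self pairs row-major: (i, j), j != i
    src <- (idx - 1L) %/% (n_nodes - 1L) + 1L
    off <- (idx - 1L) %% (n_nodes - 1L) + 1L
    tgt <- ifelse(off >= src, off + 1L, off)
    w <- runif(m, weight_range[1], weight_range[2])
    structure(list(n_nodes = as.integer(n_nodes),
                   edges = cbind(source = as.integer(src), target = as.integer(tgt)),
                   weights = w),
              class = "truth_graph")
  })
}

#' @export
print.truth_graph <- function(x, ...) {
  cat("<truth_graph> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Adjacency matrix of a ground-truth graph
#' @param truth a `truth_graph`.
#' @param labels optional channel labels (default `1:n`).
#' @return 0/1 integer matrix, rows = source, columns = target.
#' @export
truth_adjacency <- function(truth, labels = NULL) {
  n <- truth$n_nodes
  a <- matrix(0L, n, n)
  if (nrow(truth$edges)) a[truth$edges] <- 1L
  labels <- labels %||% as.character(seq_len(n))
  dimnames(a) <- list(labels, labels)
  a
}

#' Baseline renewal configuration for the spike simulator
#'
#' @param isi_family `"poisson"` (exponential inter-spike intervals) or
#'   `"gamma"`.
#' @param rate_hz target firing rate per node, recycled to the number of
#'   nodes; the default band 2-20 Hz matches medium cortical rates.
#' @param gamma_shape gamma shape (>= 1 so the hazard stays bounded);
#'   ignored for `"poisson"`.
#' @return list of class `baseline_config`.
#' @export
baseline_config <- function(isi_family = c("gamma", "poisson"), rate_hz = 8,
                            gamma_shape = 2) {
  isi_family <- match.arg(isi_family)
  if (any(rate_hz <= 0)) stop("`rate_hz` must be positive", call. = FALSE)
  if (isi_family == "gamma" && gamma_shape < 1)
    stop("`gamma_shape` must be >= 1 (hazard unbounded below 1)", call. = FALSE)
  structure(list(isi_family = isi_family, rate_hz = rate_hz,
                 gamma_shape = if (isi_family == "gamma") gamma_shape else 1),
            class = "baseline_config")
}

#' Influence kernel configuration
#'
#' The influence covariate of reference train `j` at time `t` is
#' `Z_j(t) = exp(-(t - s_j(t)) / tau_s)` where `s_j(t)` is `j`'s latest
#' spike at or before `t` (`Z_j = 0` before `j`'s first spike): an
#' exponential decay of `j`'s backward recurrence time, taking values in
#' `[0, 1]`.
#'
#' @param tau_s decay time constant in seconds (default 0.01).
#' @return list of class `influence_kernel`.
#' @export
influence_kernel <- function(tau_s = 0.01) {
  if (!is.numeric(tau_s) || tau_s <= 0) stop("`tau_s` must be > 0", call. = FALSE)
  structure(list(form = "exp_decay", tau_s = tau_s), class = "influence_kernel")
}

# Baseline hazard of the renewal ISI distribution at age u (vector-safe).
# Gamma(shape k, rate k*r) has mean ISI 1/r and hazard increasing to k*r,
# so the hazard is bounded above by `shape * rate` whenever shape >= 1.
baseline_hazard <- function(u, rate_hz, shape) {
  if (shape == 1) return(rep(rate_hz, length(u)))
  th <- shape * rate_hz
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(dgamma(u[pos], shape = shape, rate = th, log = TRUE) -
                  pgamma(u[pos], shape = shape, rate = th,
                         lower.tail = FALSE, log.p = TRUE))
  # far right tail: survival underflows; hazard has reached its asymptote
  out[!is.finite(out)] <- th
  out
}

#' Simulate coupled spike trains from a known graph
#'
#' Generates one realization of the modulated renewal network
#' `lambda_i(t) = lambda0_i(u_i(t)) * exp(sum_j w_ji Z_j(t))`, where
#' `u_i(t)` is node `i`'s backward recurrence time, `lambda0_i` the hazard
#' of its baseline ISI distribution, and `Z_j` the influence kernel of each
#' parent `j` with a `(j, i)` edge — exactly the intensity the Cox
#' connectivity estimator assumes.  Simulation is by Ogata thinning with a
#' per-node bound `shape_i * rate_i * exp(sum_j max(0, w_ji) * Z_j)`
#' refreshed after every accepted spike; between spikes all `Z_j` decay, so
#' the bound remains valid and no discretization is involved.
#'
#' @param truth a [make_ground_truth_graph()] result.
#' @param baseline a [baseline_config()]; `rate_hz` is recycled per node.
#' @param kernel an [influence_kernel()].
#' @param duration_s simulated duration in seconds.
#' @param seed RNG seed.
#' @param labels optional channel labels.
#' @return list of class `simulation_result` with elements `spikes`
#'   (a [spike_train_set()]), `truth`, and `seed`.
#' @export
simulate_spike_trains <- function(truth, baseline = baseline_config(),
                                  kernel = influence_kernel(),
                                  duration_s = 120, seed = 1, labels = NULL) {
  stopifnot(inherits(truth, "truth_graph"), inherits(baseline, "baseline_config"),
            inherits(kernel, "influence_kernel"))
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (!all(is.finite(truth$weights))) stop("coupling weights must be finite", call. = FALSE)
  n <- truth$n_nodes
  rate <- rep_len(baseline$rate_hz, n)
  shape <- baseline$gamma_shape
  tau <- kernel$tau_s
  lam0max <- shape * rate
  # weight matrices: w[j, i] = coupling j -> i
  w <- matrix(0, n, n)
  if (nrow(truth$edges)) w[truth$edges] <- truth$weights
  wpos <- pmax(w, 0)
  parents <- lapply(seq_len(n), function(i) which(w[, i] != 0))
  bound_cap <- 1e6
  spikes <- with_seed(seed, {
    last <- rep(0, n)          # renewal age measured from session start
    seen <- rep(FALSE, n)      # Z_j = 0 until j's first spike
    out <- vector("list", n)
    for (i in seq_len(n)) out[[i]] <- numeric(0)
    t_now <- 0
    repeat {
      z <- ifelse(seen, exp(-(t_now - last) / tau), 0)
      b <- lam0max * exp(as.vector(crossprod(wpos, z)))  # per-node bound at t_now
      if (any(b > bound_cap))
        stop("intensity bound exceeds ", bound_cap, " Hz at node ",
             which.max(b), "; weights too large", call. = FALSE)
      btot <- sum(b)
      accepted <- FALSE
      t_cand <- t_now
      while (!accepted) {
        t_cand <- t_cand + rexp(1, btot)
        if (t_cand >= duration_s) break
        i <- sample.int(n, 1, prob = b)
        lam0 <- baseline_hazard(t_cand - last[i], rate[i], shape)
        pj <- parents[[i]]
        zc <- if (length(pj)) ifelse(seen[pj], exp(-(t_cand - last[pj]) / tau), 0) else numeric(0)
        lam <- lam0 * exp(sum(w[pj, i] * zc))
        if (runif(1) * b[i] <= lam) accepted <- TRUE
      }
      if (!accepted) break                      # ran past the horizon
      out[[i]] <- c(out[[i]], t_cand)
      last[i] <- t_cand
      seen[i] <- TRUE
      t_now <- t_cand
    }
    out
  })
  labels <- labels %||% as.character(seq_len(n))
  names(spikes) <- labels
  structure(list(spikes = spike_train_set(spikes, duration_s),
                 truth = truth, seed = seed),
            class = "simulation_result")
}

#' Simulate a full multi-stimulus recording session
#'
#' For each stimulus, a continuous realization of its ground-truth network
#' is simulated for `n_trials * trial_s` seconds and then cut into
#' `n_trials` consecutive chunks; the chunks are interleaved into a session
#' timeline in randomized trial order, separated by silent gaps.  Because
#' each stimulus's activity is generated on its own continuous clock,
#' re-concatenating the trials with [extract_stimulus_segments()] recovers
#' that continuous realization exactly.
#'
#' @param truth_per_stimulus named list of `truth_graph` objects, one per
#'   stimulus.
#' @param n_trials trials per stimulus (default 20).
#' @param trial_s trial length in seconds (default 6).
#' @param gap_s silent gap between consecutive trials (default 1).
#' @param baseline,kernel,seed,labels passed to [simulate_spike_trains()].
#' @return list with `spikes` (session [spike_train_set()]), `schedule`
#'   (data frame `stimulus_id,trial_index,start_s,end_s`), `truth`
#'   (the input list), and `seed`.
#' @export
simulate_stimulus_session <- function(truth_per_stimulus, n_trials = 20,
                                      trial_s = 6, gap_s = 1,
                                      baseline = baseline_config(),
                                      kernel = influence_kernel(),
                                      seed = 1, labels = NULL) {
  if (!is.list(truth_per_stimulus) || length(truth_per_stimulus) == 0L)
    stop("`truth_per_stimulus` must be a non-empty list", call. = FALSE)
  if (is.null(names(truth_per_stimulus)))
    names(truth_per_stimulus) <- as.character(seq_along(truth_per_stimulus))
  if (n_trials < 1 || trial_s <= 0 || gap_s < 0)
    stop("invalid trial structure parameters", call. = FALSE)
  stim_ids <- names(truth_per_stimulus)
  n_stim <- length(stim_ids)
  n <- truth_per_stimulus[[1]]$n_nodes
  if (!all(vapply(truth_per_stimulus, function(g) g$n_nodes, integer(1)) == n))
    stop("all stimuli must share the same node set", call. = FALSE)
  seeds <- derive_seeds(seed, n_stim + 1L)
  sims <- lapply(seq_len(n_stim), function(k)
    simulate_spike_trains(truth_per_stimulus[[k]], baseline, kernel,
                          duration_s = n_trials * trial_s, seed = seeds[k],
                          labels = labels))
  # randomized trial order over the session
  order_vec <- with_seed(seeds[n_stim + 1L],
                         sample(rep(stim_ids, each = n_trials)))
  slot_len <- trial_s + gap_s
  slot_start <- (seq_along(order_vec) - 1) * slot_len
  trial_idx <- stats::ave(seq_along(order_vec), order_vec, FUN = seq_along)
  schedule <- data.frame(stimulus_id = order_vec, trial_index = trial_idx,
                         start_s = slot_start, end_s = slot_start + trial_s)
  labels <- labels %||% as.character(seq_len(n))
  session <- lapply(labels, function(ch) {
    pieces <- lapply(seq_len(nrow(schedule)), function(r) {
      s <- schedule$stimulus_id[r]
      j <- schedule$trial_index[r]
      x <- sims[[match(s, stim_ids)]]$spikes$spikes[[ch]]
      chunk <- x[x >= (j - 1) * trial_s & x < j * trial_s]
      chunk - (j - 1) * trial_s + schedule$start_s[r]
    })
    sort(unlist(pieces))
  })
  names(session) <- labels
  duration <- max(schedule$end_s)  # session ends with the last trial
  list(spikes = spike_train_set(session, duration),
       schedule = schedule,
       truth = truth_per_stimulus,
       seed = seed)
}

#' Write a ground-truth graph as an edge list
#'
#' Columns `source,target,weight`; companion reader returns the same
#' `truth_graph` structure.
#'
#' @param truth a `truth_graph`.
#' @param path CSV path.
#' @export
write_truth_graph <- function(truth, path) {
  df <- data.frame(source = truth$edges[, "source"],
                   target = truth$edges[, "target"],
                   weight = truth$weights)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_graph
#' @param n_nodes node count of the stored graph.
#' @export
read_truth_graph <- function(path, n_nodes) {
  df <- read.csv(path)
  structure(list(n_nodes = as.integer(n_nodes),
                 edges = cbind(source = as.integer(df$source),
                               target = as.integer(df$target)),
                 weights = as.numeric(df$weight)),
            class = "truth_graph")
}
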
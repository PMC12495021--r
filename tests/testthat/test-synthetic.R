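test_that("ground-truth graphs honour density, exclusions and the seed", {
  g0 <- make_ground_truth_graph(29, 0, seed = 1)
  expect_equal(nrow(g0$edges), 0)

  g <- make_ground_truth_graph(29, 0.1429, seed = 1)
  expect_equal(nrow(g$edges), 116)  # round(0.1429 * 29 * 28)

  for (s in 1:5) {
    gs <- make_ground_truth_graph(12, 0.2, seed = s)
    expect_false(any(gs$edges[, 1] == gs$edges[, 2]))
    expect_false(anyDuplicated(paste(gs$edges[, 1], gs$edges[, 2])) > 0)
  }
  expect_identical(make_ground_truth_graph(10, 0.3, seed = 9),
                   make_ground_truth_graph(10, 0.3, seed = 9))
  expect_error(make_ground_truth_graph(10, 1.2), "density")
})

test_that("uncoupled Poisson trains realize their nominal rate", {
  g0 <- make_ground_truth_graph(4, 0, seed = 1)
  expected <- 10 * 120
  counts <- sapply(1:10, function(s) {
    sim <- simulate_spike_trains(g0, baseline_config("poisson", 10),
                                 duration_s = 120, seed = s)
    vapply(sim$spikes$spikes, length, integer(1))
  })
  # per-channel Poisson counts: all within 4 sigma, grand mean within 3 SE
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected / length(counts)))
})

test_that("simulator output is deterministic and bitwise reproducible", {
  g <- make_ground_truth_graph(5, 0.2, seed = 3)
  s1 <- simulate_spike_trains(g, duration_s = 20, seed = 11)
  s2 <- simulate_spike_trains(g, duration_s = 20, seed = 11)
  expect_identical(s1$spikes, s2$spikes)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(s1$spikes, p1)
  write_spike_table(s2$spikes, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(
    s1$spikes, simulate_spike_trains(g, duration_s = 20, seed = 12)$spikes))
})

test_that("uncoupled trains are uncorrelated in 1 s count bins", {
  g0 <- make_ground_truth_graph(6, 0, seed = 1)
  sim <- simulate_spike_trains(g0, baseline_config("gamma", 8, 2),
                               duration_s = 120, seed = 5)
  bins <- seq(0, 120, by = 1)
  counts <- sapply(sim$spikes$spikes, function(x) table(cut(x, bins)))
  r <- cor(counts)
  expect_true(all(abs(r[upper.tri(r)]) < 3 / sqrt(length(bins) - 1)))
})

test_that("an excitatory edge raises the downstream rate", {
  base <- truth_from_edges(2, NULL, numeric(0))
  coupled <- truth_from_edges(2, rbind(c(1, 2)), 1.5)
  s_base <- simulate_spike_trains(base, baseline_config("gamma", 8, 2),
                                  duration_s = 120, seed = 77)
  s_coup <- simulate_spike_trains(coupled, baseline_config("gamma", 8, 2),
                                  duration_s = 120, seed = 77)
  expect_gt(length(s_coup$spikes$spikes[[2]]), length(s_base$spikes$spikes[[2]]))
})

test_that("gamma baseline ISIs match the configured renewal distribution", {
  g0 <- make_ground_truth_graph(2, 0, seed = 1)
  sim <- simulate_spike_trains(g0, baseline_config("gamma", 12, 2),
                               duration_s = 500, seed = 31)
  isi <- unlist(lapply(sim$spikes$spikes, diff), use.names = FALSE)
  expect_gt(length(isi), 5000)
  ks <- suppressWarnings(ks.test(isi, "pgamma", shape = 2, rate = 2 * 12))
  expect_gt(ks$p.value, 0.01)
})

test_that("oversized couplings raise a simulation error naming the node", {
  g <- truth_from_edges(3, rbind(c(1, 3), c(2, 3)), c(12, 12))
  expect_error(
    simulate_spike_trains(g, baseline_config("poisson", 10), duration_s = 5,
                          seed = 1),
    "node 3")
})

test_that("stimulus sessions have the requested trial structure", {
  truths <- lapply(1:6, function(k) make_ground_truth_graph(5, 0.1, seed = k))
  names(truths) <- as.character(1:6)
  sess <- simulate_stimulus_session(truths, n_trials = 20, trial_s = 6,
                                    gap_s = 1, seed = 4)
  sched <- sess$schedule
  expect_equal(nrow(sched), 120)
  expect_true(all(table(sched$stimulus_id) == 20))
  expect_equal(sched$end_s - sched$start_s, rep(6, 120))
  # pairwise disjoint intervals
  o <- order(sched$start_s)
  expect_true(all(sched$start_s[o][-1] >= sched$end_s[o][-120]))
  # deterministic under the seed
  sess2 <- simulate_stimulus_session(truths, n_trials = 20, trial_s = 6,
                                     gap_s = 1, seed = 4)
  expect_identical(sess$spikes, sess2$spikes)
  expect_identical(sess$schedule, sess2$schedule)
})

test_that("a gapless single-stimulus session spans the whole timeline", {
  truths <- list(`1` = make_ground_truth_graph(4, 0.1, seed = 2))
  sess <- simulate_stimulus_session(truths, n_trials = 5, trial_s = 4,
                                    gap_s = 0, seed = 8)
  expect_equal(max(sess$schedule$end_s), 20)
  expect_equal(sess$spikes$duration_s, 20)
  expect_equal(min(sess$schedule$start_s), 0)
})

test_that("extracted segments reproduce the generated per-stimulus activity", {
  truths <- lapply(1:2, function(k)
    make_ground_truth_graph(4, 0.15, c(1, 1.5), seed = k))
  names(truths) <- c("1", "2")
  sess <- simulate_stimulus_session(truths, n_trials = 6, trial_s = 5,
                                    gap_s = 2, seed = 13)
  for (s in c("1", "2")) {
    seg <- extract_stimulus_segments(sess$spikes, sess$schedule, s)
    # oracle: filter the session directly, interval by interval
    sel <- sess$schedule[sess$schedule$stimulus_id == s, ]
    sel <- sel[order(sel$start_s), ]
    for (ch in channel_ids(sess$spikes)) {
      x <- sess$spikes$spikes[[ch]]
      mapped <- unlist(lapply(seq_len(nrow(sel)), function(k) {
        inside <- x[x >= sel$start_s[k] & x < sel$end_s[k]]
        inside - sel$start_s[k] + (k - 1) * 5
      }))
      expect_equal(seg$spikes[[ch]], as.numeric(mapped))
    }
  }
})

test_that("the P1 sampler matches its analytic dyad distribution", {
  # degenerate limit: theta -> -inf gives the empty graph
  expect_equal(sum(sample_p1_network(-50, 0, numeric(5), numeric(5), seed = 1)), 0)

  # rho = 0, alpha = beta = 0: edges are independent Bernoulli(e^th/(1+e^th))
  th <- -1.5
  p <- exp(th) / (1 + exp(th))
  n <- 40
  m <- sum(sample_p1_network(th, 0, numeric(n), numeric(n), seed = 2))
  npair <- n * (n - 1)
  expect_lt(abs(m - npair * p), 3 * sqrt(npair * p * (1 - p)))

  # one dyad sampled repeatedly matches the four-cell probabilities
  probs <- p1_dyad_probs(-0.5, 0.8, 0.3, -0.2, 0.1, 0.4)
  draws <- vapply(1:4000, function(s) {
    a <- sample_p1_network(-0.5, 0.8, c(0.3, -0.2), c(0.1, 0.4), seed = s)
    1L + a[1, 2] + 2L * a[2, 1]
  }, integer(1))
  freq <- tabulate(draws, 4) / 4000
  expect_true(all(abs(freq - probs) < 3 * sqrt(probs * (1 - probs) / 4000)))
})
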
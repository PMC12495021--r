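test_that("influence covariates follow the exponential-decay kernel", {
  k <- influence_kernel(0.02)
  ref <- c(1, 2, 3.5)
  expect_equal(influence_covariates(ref, c(2), k), 1)           # at a spike
  expect_equal(influence_covariates(ref, c(1.02), k), exp(-1))  # one tau later
  expect_equal(influence_covariates(ref, c(0.5), k), 0)         # before first

  set.seed(5)
  ref2 <- sort(runif(50, 0, 10))
  times <- sort(runif(200, 0, 12))
  expect_equal(influence_covariates(ref2, times, k),
               oracle_influence(ref2, times, 0.02))
  expect_error(influence_covariates(c(2, 1), times, k), "sorted")
})

test_that("risk sets partition the target timeline into renewal observations", {
  obs <- build_risk_sets(c(1, 2, 4), 5)
  expect_equal(obs$length, c(1, 1, 2, 1))
  expect_equal(obs$event, c(0L, 1L, 1L, 0L))
  expect_equal(obs$start, c(0, 1, 2, 4))
  expect_error(build_risk_sets(c(1), 5), "insufficient events")

  # boundary-spanning intervals censored when split_at is given
  obs2 <- build_risk_sets(c(1, 2.5, 4), 6, split_at = 3)
  # the ISI (2.5, 4] crosses 3: censored at 3 with length 0.5
  crossing <- obs2[obs2$start == 2.5, ]
  expect_equal(crossing$length, 0.5)
  expect_equal(crossing$event, 0L)
})

test_that("the partial likelihood matches closed forms and finite differences", {
  # at beta = 0 the loglik is -sum over events of log |risk set|
  set.seed(11)
  g <- make_ground_truth_graph(4, 0.25, seed = 2)
  sim <- simulate_spike_trains(g, baseline_config("gamma", 6, 2),
                               duration_s = 40, seed = 3)
  sp <- sim$spikes$spikes
  obs <- build_risk_sets(sp[[1]], 40)
  refs <- sp[2:4]
  k <- influence_kernel(0.01)
  pl0 <- cox_partial_loglik(obs, refs, k, beta = c(0, 0, 0))
  risk_sizes <- vapply(obs$length[obs$event == 1],
                       function(u) sum(obs$length >= u), numeric(1))
  expect_equal(pl0$loglik, -sum(log(risk_sizes)))

  # a single event whose risk set is itself contributes 0
  solo <- build_risk_sets(c(0.5, 2.0), 2.5)
  pl1 <- cox_partial_loglik(solo, list(c(0.3)), k, beta = 0.7)
  expect_equal(pl1$loglik, 0)

  # analytic gradient and Hessian against central differences
  b0 <- c(0.4, -0.3, 0.2)
  pl <- cox_partial_loglik(obs, refs, k, b0)
  eps <- 1e-5
  for (j in 1:3) {
    bp <- b0; bp[j] <- bp[j] + eps
    bm <- b0; bm[j] <- bm[j] - eps
    fd <- (cox_partial_loglik(obs, refs, k, bp)$loglik -
           cox_partial_loglik(obs, refs, k, bm)$loglik) / (2 * eps)
    expect_equal(pl$gradient[j], fd, tolerance = 1e-6)
    gd <- (cox_partial_loglik(obs, refs, k, bp)$gradient -
           cox_partial_loglik(obs, refs, k, bm)$gradient) / (2 * eps)
    expect_equal(pl$hessian[, j], gd, tolerance = 1e-5)
  }
})

test_that("the fit agrees with coxph on the counting-process formulation", {
  skip_if_not_installed("survival")
  g <- truth_from_edges(3, rbind(c(2, 1), c(3, 1)), c(1.0, -0.5))
  sim <- simulate_spike_trains(g, baseline_config("gamma", 7, 2),
                               duration_s = 60, seed = 19)
  sp <- sim$spikes$spikes
  k <- influence_kernel(0.01)
  obs <- build_risk_sets(sp[[1]], 60)
  fit <- fit_target("1", sim$spikes, k)

  zfun <- function(ref) {
    force(ref)
    function(x, t, ...) {
      # x carries the observation's absolute start; survival time t is the
      # elapsed backward-recurrence time
      idx <- findInterval(x + t, ref)
      out <- numeric(length(t))
      has <- idx >= 1
      out[has] <- exp(-((x + t)[has] - ref[idx[has]]) / 0.01)
      out
    }
  }
  df <- data.frame(time = obs$length, status = obs$event, start1 = obs$start)
  cph <- survival::coxph(
    survival::Surv(time, status) ~ tt(start1) + tt(start2),
    data = transform(df, start2 = start1),
    tt = list(zfun(sp[[2]]), zfun(sp[[3]])), ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-4)
  expect_equal(fit$loglik, cph$loglik[2], tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cph)))), tolerance = 1e-3)
})

test_that("degenerate references are dropped with warnings", {
  g0 <- make_ground_truth_graph(3, 0, seed = 1)
  sim <- simulate_spike_trains(g0, baseline_config("poisson", 8),
                               duration_s = 60, seed = 23)
  sp <- sim$spikes$spikes
  sp[["zero"]] <- numeric(0)
  sts <- spike_train_set(sp, 60)
  expect_warning(fit <- fit_target("1", sts, influence_kernel(0.01)),
                 "no spikes")
  expect_false("zero" %in% fit$reference_ids)
  expect_true(fit$converged)

  # a duplicated reference makes the information singular; one copy is dropped
  sp2 <- sim$spikes$spikes
  sp2[["dup"]] <- sp2[["2"]]
  sts2 <- spike_train_set(sp2, 60)
  expect_warning(fit2 <- fit_target("1", sts2, influence_kernel(0.01)),
                 "singular")
  expect_true(fit2$converged)
  expect_lt(length(fit2$reference_ids), 3)

  expect_error(fit_target("1", sts, influence_kernel(0.01), min_events = 1e5),
               "insufficient events")
})

test_that("Newton iterations increase the partial likelihood monotonically", {
  g <- truth_from_edges(3, rbind(c(2, 1)), 1.2)
  sim <- simulate_spike_trains(g, baseline_config("gamma", 8, 2),
                               duration_s = 40, seed = 29)
  sp <- sim$spikes$spikes
  obs <- build_risk_sets(sp[[1]], 40)
  refs <- sp[2:3]
  k <- influence_kernel(0.01)
  # replay Newton with step halving in R and record the loglik path
  beta <- c(0, 0)
  lls <- numeric(0)
  for (it in 1:25) {
    pl <- cox_partial_loglik(obs, refs, k, beta)
    lls <- c(lls, pl$loglik)
    step <- solve(-pl$hessian, pl$gradient)
    h <- 0
    repeat {
      cand <- beta + step / 2^h
      if (cox_partial_loglik(obs, refs, k, cand)$loglik >= pl$loglik - 1e-12 ||
          h > 30) break
      h <- h + 1
    }
    beta <- beta + step / 2^h
  }
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("connectivity estimates have a clean diagonal and recover structure", {
  g <- make_ground_truth_graph(6, 0.15, c(1.0, 1.5), seed = 11)
  sim <- simulate_spike_trains(g, baseline_config("gamma", 8, 2),
                               influence_kernel(0.01), 120, seed = 21)
  conn <- estimate_connectivity(sim$spikes, influence_kernel(0.01))
  expect_true(all(diag(conn) == 0))
  expect_true(all(conn %in% c(0L, 1L)))
  tru <- truth_adjacency(g)
  # all planted edges recovered at this coupling strength and duration
  expect_true(all(conn[tru == 1] == 1))
  # multiple-testing corrections can only remove edges
  conn_bh <- estimate_connectivity(sim$spikes, influence_kernel(0.01),
                                   correction = "bh")
  conn_bf <- estimate_connectivity(sim$spikes, influence_kernel(0.01),
                                   correction = "bonferroni")
  expect_true(all(conn_bh <= conn))
  expect_true(all(conn_bf <= conn_bh))
  rep <- connectivity_report(conn)
  expect_equal(sum(rep$called), sum(conn))
})

test_that("circularly shifting a reference destroys its called edge", {
  g <- truth_from_edges(3, rbind(c(2, 1)), 1.5)
  sim <- simulate_spike_trains(g, baseline_config("gamma", 8, 2),
                               influence_kernel(0.01), 120, seed = 41)
  sp <- sim$spikes$spikes
  fit <- fit_target("1", sim$spikes, influence_kernel(0.01))
  expect_gt(fit$ci_low[["2"]], 0)  # the true edge is called
  # circular shift by >> 5 tau breaks the temporal alignment
  shift <- 1.7
  sp[["2"]] <- sort((sp[["2"]] + shift) %% 120)
  fit2 <- fit_target("1", spike_train_set(sp, 120), influence_kernel(0.01))
  expect_true(fit2$ci_low[["2"]] <= 0 && fit2$ci_high[["2"]] >= 0)
})

test_that("the estimator tightens with duration as 1/sqrt(T)", {
  g <- truth_from_edges(2, rbind(c(1, 2)), 1.0)
  k <- influence_kernel(0.01)
  se_at <- function(T, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_spike_trains(g, baseline_config("gamma", 8, 2), k,
                                   duration_s = T, seed = s)
      fit_target("2", sim$spikes, k)$se[[1]]
    }, numeric(1)))
  }
  se60 <- se_at(60, 1:3)
  se240 <- se_at(240, 1:3)
  expect_equal(se240 / se60, 0.5, tolerance = 0.15)
})
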
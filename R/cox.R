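#' Influence covariate of a reference spike train
#'
#' Evaluates `Z(t) = exp(-(t - s(t)) / tau_s)` at each requested time,
#' where `s(t)` is the latest reference spike at or before `t`; `Z(t) = 0`
#' before the first reference spike.  Both inputs must be sorted; the
#' lookup is a single vectorized interval search.
#'
#' @param ref_spikes sorted reference spike times (seconds).
#' @param eval_times sorted evaluation times.
#' @param kernel an [influence_kernel()].
#' @return numeric vector of covariate values in `[0, 1]`.
#' @export
influence_covariates <- function(ref_spikes, eval_times, kernel = influence_kernel()) {
  stopifnot(inherits(kernel, "influence_kernel"))
  if (is.unsorted(ref_spikes) || is.unsorted(eval_times))
    stop("inputs must be sorted", call. = FALSE)
  idx <- findInterval(eval_times, ref_spikes)
  z <- numeric(length(eval_times))
  has <- idx >= 1L
  z[has] <- exp(-(eval_times[has] - ref_spikes[idx[has]]) / kernel$tau_s)
  z
}

#' Build renewal observations (risk sets) for one target train
#'
#' Each inter-spike interval of the target becomes one observation whose
#' "survival time" is the interval length, with an event at its end; the
#' leading interval (session start to first spike) and trailing interval
#' (last spike to session end) are right-censored.  The risk set of an
#' event at elapsed time `u` is every observation with survival time
#' `>= u`.  If `split_at` boundary times are supplied (see
#' [extract_stimulus_segments()]), intervals spanning a boundary are
#' censored at the first boundary they cross and the remainder is dropped,
#' since the renewal age across a concatenation gap is not observed.
#'
#' @param target_spikes sorted spike times of the target train.
#' @param duration_s session duration.
#' @param split_at optional increasing boundary times at which to censor.
#' @return data frame with columns `start` (absolute interval start),
#'   `length`, `event` (0/1).
#' @export
build_risk_sets <- function(target_spikes, duration_s, split_at = NULL) {
  ts <- as.numeric(target_spikes)
  if (length(ts) < 2) stop("insufficient events: need >= 2 target spikes", call. = FALSE)
  start <- c(0, ts)
  end <- c(ts, duration_s)
  event <- c(0L, rep(1L, length(ts) - 1L), 0L)
  obs <- data.frame(start = start, length = end - start, event = event)
  obs <- obs[obs$length > 0, , drop = FALSE]
  if (!is.null(split_at) && length(split_at)) {
    split_at <- sort(split_at)
    iend <- obs$start + obs$length
    b <- vapply(seq_len(nrow(obs)), function(k) {
      inside <- split_at[split_at > obs$start[k] & split_at < iend[k]]
      if (length(inside)) inside[1] else NA_real_
    }, numeric(1))
    cross <- !is.na(b)
    obs$length[cross] <- b[cross] - obs$start[cross]
    obs$event[cross] <- 0L
  }
  rownames(obs) <- NULL
  obs
}

#' Cox partial log-likelihood for the modulated renewal model
#'
#' Computes the partial log-likelihood
#' `l(beta) = sum_events [beta' Z_event - log sum_{k in risk set}
#' exp(beta' Z_k(u_event))]`, with covariates of observation `k` at event
#' elapsed time `u` evaluated at absolute session time `start_k + u`, plus
#' the analytic gradient and Hessian.  Ties use the Breslow approximation;
#' each risk set's linear predictors are max-centred before
#' exponentiation.
#'
#' @param observations data frame from [build_risk_sets()].
#' @param ref_spikes list of sorted reference spike-time vectors.
#' @param kernel an [influence_kernel()].
#' @param beta coefficient vector, one per reference.
#' @return list with `loglik`, `gradient`, `hessian`.
#' @export
cox_partial_loglik <- function(observations, ref_spikes, kernel = influence_kernel(),
                               beta = numeric(length(ref_spikes))) {
  stopifnot(is.data.frame(observations),
            all(c("start", "length", "event") %in% names(observations)))
  if (length(beta) != length(ref_spikes))
    stop("`beta` must have one entry per reference", call. = FALSE)
  cox_loglik_cpp(observations$start, observations$length,
                 as.integer(observations$event), ref_spikes,
                 kernel$tau_s, as.numeric(beta))
}

#' Fit all reference influences on one target train
#'
#' Maximizes the modulated-renewal partial likelihood jointly over all
#' reference coefficients by Newton-Raphson with step halving, starting
#' from `beta = 0`.  Standard errors come from the inverse observed
#' information; edges are called from two-sided Wald confidence intervals.
#' References with no spikes are dropped with a warning; if the observed
#' information is singular, the reference dominating its null direction is
#' dropped (warning) and the fit restarted.
#'
#' @param target_id label of the target channel.
#' @param spikes a [spike_train_set()] containing target and references.
#' @param kernel an [influence_kernel()].
#' @param alpha_level two-sided level for the Wald intervals (default 0.05).
#' @param min_events minimum target spike count (default 30).
#' @param reference_ids references to include (default: all other channels).
#' @param split_at optional censoring boundaries, see [build_risk_sets()].
#' @return object of class `cox_fit`: coefficients, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `loglik`, `converged`, `n_events`,
#'   `dropped` (labels of discarded references).
#' @export
fit_target <- function(target_id, spikes, kernel = influence_kernel(),
                       alpha_level = 0.05, min_events = 30,
                       reference_ids = NULL, split_at = NULL) {
  stopifnot(is.spike_train_set(spikes))
  target_id <- as.character(target_id)
  if (!target_id %in% names(spikes$spikes))
    stop("unknown target: ", target_id, call. = FALSE)
  reference_ids <- as.character(reference_ids %||%
                                  setdiff(names(spikes$spikes), target_id))
  ts <- spikes$spikes[[target_id]]
  if (length(ts) < min_events)
    stop("insufficient events: target ", target_id, " has ", length(ts),
         " spikes (< ", min_events, ")", call. = FALSE)
  obs <- build_risk_sets(ts, spikes$duration_s, split_at = split_at)
  empty <- vapply(spikes$spikes[reference_ids], length, integer(1)) == 0L
  dropped <- character(0)
  if (any(empty)) {
    warning("dropping reference(s) with no spikes: ",
            paste(reference_ids[empty], collapse = ", "), call. = FALSE)
    dropped <- reference_ids[empty]
    reference_ids <- reference_ids[!empty]
  }
  repeat {
    refs <- spikes$spikes[reference_ids]
    p <- length(refs)
    if (p == 0L) stop("no usable references", call. = FALSE)
    nf <- cox_newton_cpp(obs$start, obs$length, as.integer(obs$event),
                         refs, kernel$tau_s, 100L, 1e-8)
    info <- -nf$hessian
    ev <- eigen(info, symmetric = TRUE)
    if (nf$singular || min(ev$values) < 1e-10 * max(abs(ev$values), 1)) {
      # name the reference dominating the (near-)null direction
      v <- ev$vectors[, which.min(ev$values)]
      singular_j <- which.max(abs(v))
      warning("singular information; dropping reference ",
              reference_ids[singular_j], call. = FALSE)
      dropped <- c(dropped, reference_ids[singular_j])
      reference_ids <- reference_ids[-singular_j]
      next
    }
    beta <- nf$beta
    fit <- nf
    converged <- nf$converged
    se <- rep(NA_real_, p)
    if (converged) {
      vc <- tryCatch(solve(-fit$hessian), error = function(e) NULL)
      if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
    }
    zq <- qnorm(1 - alpha_level / 2)
    zstat <- beta / se
    res <- structure(list(
      target_id = target_id,
      reference_ids = reference_ids,
      beta = stats::setNames(beta, reference_ids),
      se = stats::setNames(se, reference_ids),
      ci_low = stats::setNames(beta - zq * se, reference_ids),
      ci_high = stats::setNames(beta + zq * se, reference_ids),
      p_value = stats::setNames(2 * pnorm(-abs(zstat)), reference_ids),
      loglik = fit$loglik,
      converged = converged,
      n_events = sum(obs$event),
      alpha_level = alpha_level,
      dropped = dropped), class = "cox_fit")
    return(res)
  }
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> target ", x$target_id, ": ", x$n_events, " events, ",
      length(x$reference_ids), " references, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  df <- data.frame(reference = x$reference_ids, beta = round(x$beta, 4),
                   se = round(x$se, 4), ci_low = round(x$ci_low, 4),
                   ci_high = round(x$ci_high, 4),
                   called = x$ci_low > 0 | x$ci_high < 0, row.names = NULL)
  print(df)
  invisible(x)
}

#' Estimate the binary directed connectivity matrix
#'
#' Runs [fit_target()] once per channel (each channel in turn is the
#' target, all others the references) and calls edge `i -> j` when the
#' Wald interval of reference `i` in target `j`'s fit excludes zero after
#' the configured multiple-testing correction.  The diagonal is forced to
#' zero.  Targets whose fit fails or does not converge contribute an empty
#' column, with a warning.
#'
#' @param spikes a [spike_train_set()] (>= 3 channels).
#' @param kernel an [influence_kernel()].
#' @param alpha_level edge-call level (default 0.05).
#' @param correction `"none"` (default), `"bonferroni"`, or `"bh"`
#'   (Benjamini-Hochberg), applied to the pooled Wald p-values of all
#'   reference-target tests.
#' @param min_events minimum target spike count (default 30).
#' @param mode `"joint"` (all references in one fit; default) or
#'   `"pairwise"` (one reference at a time, for comparison).
#' @param split_at optional censoring boundaries, see [build_risk_sets()].
#' @return 0/1 integer matrix (rows = source/reference, columns = target)
#'   of class `connectivity_matrix`, with the per-target fits in attribute
#'   `"fits"` and estimated coefficient signs in attribute `"sign"`.
#' @export
estimate_connectivity <- function(spikes, kernel = influence_kernel(),
                                  alpha_level = 0.05,
                                  correction = c("none", "bonferroni", "bh"),
                                  min_events = 30, mode = c("joint", "pairwise"),
                                  split_at = NULL) {
  stopifnot(is.spike_train_set(spikes))
  correction <- match.arg(correction)
  mode <- match.arg(mode)
  labs <- names(spikes$spikes)
  n <- length(labs)
  if (n < 3) stop("need at least 3 channels", call. = FALSE)
  a <- matrix(0L, n, n, dimnames = list(labs, labs))
  sgn <- matrix(0, n, n, dimnames = list(labs, labs))
  pmat <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  fits <- stats::setNames(vector("list", n), labs)
  for (tg in labs) {
    f <- tryCatch({
      if (mode == "joint") {
        fit_target(tg, spikes, kernel, alpha_level, min_events,
                   split_at = split_at)
      } else {
        refs <- setdiff(labs, tg)
        parts <- lapply(refs, function(r)
          fit_target(tg, spikes, kernel, alpha_level, min_events,
                     reference_ids = r, split_at = split_at))
        merge_pairwise_fits(tg, parts)
      }
    }, error = function(e) {
      warning("target ", tg, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    fits[[tg]] <- f
    if (is.null(f) || !f$converged) {
      if (!is.null(f) && !f$converged)
        warning("target ", tg, ": fit did not converge; no edges called",
                call. = FALSE)
      next
    }
    pmat[f$reference_ids, tg] <- f$p_value
    sgn[f$reference_ids, tg] <- sign(f$beta)
  }
  padj <- pmat
  idx <- which(!is.na(pmat))
  if (length(idx)) {
    method <- switch(correction, none = "none", bonferroni = "bonferroni", bh = "BH")
    padj[idx] <- p.adjust(pmat[idx], method = method)
  }
  a[!is.na(padj) & padj < alpha_level] <- 1L
  diag(a) <- 0L
  structure(a, class = c("connectivity_matrix", class(a)),
            fits = fits, sign = sgn, p_value = pmat,
            alpha_level = alpha_level, correction = correction)
}

# Combine single-reference fits into one cox_fit-shaped record.
merge_pairwise_fits <- function(target_id, parts) {
  ref <- vapply(parts, function(f) f$reference_ids, character(1))
  structure(list(
    target_id = target_id,
    reference_ids = ref,
    beta = stats::setNames(vapply(parts, function(f) unname(f$beta), numeric(1)), ref),
    se = stats::setNames(vapply(parts, function(f) unname(f$se), numeric(1)), ref),
    ci_low = stats::setNames(vapply(parts, function(f) unname(f$ci_low), numeric(1)), ref),
    ci_high = stats::setNames(vapply(parts, function(f) unname(f$ci_high), numeric(1)), ref),
    p_value = stats::setNames(vapply(parts, function(f) unname(f$p_value), numeric(1)), ref),
    loglik = sum(vapply(parts, function(f) f$loglik, numeric(1))),
    converged = all(vapply(parts, function(f) f$converged, logical(1))),
    n_events = parts[[1]]$n_events,
    alpha_level = parts[[1]]$alpha_level,
    dropped = unlist(lapply(parts, function(f) f$dropped))), class = "cox_fit")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x), " channels, ", sum(x),
      " edges (density ", round(sum(x) / (nrow(x) * (nrow(x) - 1)), 4), ")\n",
      sep = "")
  invisible(x)
}

#' Per-target fit report as a data frame
#'
#' @param x a `connectivity_matrix` from [estimate_connectivity()].
#' @return data frame with one row per (reference, target) pair:
#'   `reference`, `target`, `beta`, `se`, `ci_low`, `ci_high`, `called`.
#' @export
connectivity_report <- function(x) {
  fits <- attr(x, "fits")
  rows <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    data.frame(reference = f$reference_ids, target = f$target_id,
               beta = unname(f$beta), se = unname(f$se),
               ci_low = unname(f$ci_low), ci_high = unname(f$ci_high),
               called = x[cbind(f$reference_ids, rep(f$target_id, length(f$reference_ids)))] == 1L,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
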
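#' Firing-rate table across stimuli
#'
#' Rate = spike count divided by the session's effective duration, per
#' channel and per stimulus.
#'
#' @param sessions named list of [spike_train_set()] objects, one per
#'   stimulus (same channel labels in each).
#' @return numeric matrix, channels x stimuli (Hz).
#' @export
rate_table <- function(sessions) {
  if (!is.list(sessions) || length(sessions) == 0L)
    stop("`sessions` must be a non-empty list", call. = FALSE)
  labs <- channel_ids(sessions[[1]])
  stim <- names(sessions) %||% as.character(seq_along(sessions))
  out <- matrix(NA_real_, length(labs), length(sessions),
                dimnames = list(labs, stim))
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    stopifnot(is.spike_train_set(s))
    if (!identical(channel_ids(s), labs))
      stop("all sessions must share channel labels", call. = FALSE)
    if (s$duration_s <= 0) stop("zero-duration session", call. = FALSE)
    out[, k] <- vapply(s$spikes, length, integer(1)) / s$duration_s
  }
  out
}

#' Most active channels under one stimulus
#'
#' Top-`k` channels by firing rate, descending, ties broken by label order
#' as given in the table.  Apply any outlier exclusion to the table rows
#' before ranking.
#'
#' @param table rate matrix from [rate_table()] (channels x stimuli).
#' @param stimulus column name or index.
#' @param k list length (default 5).
#' @return character vector of channel labels.
#' @export
top_active <- function(table, stimulus, k = 5) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  r <- table[, stimulus]
  if (k > length(r)) {
    warning("k exceeds the channel count; returning the full ranking",
            call. = FALSE)
    k <- length(r)
  }
  rownames(table)[order(-r, seq_along(r))][seq_len(k)]
}

#' Cross-stimulus correlation of activity patterns
#'
#' Pearson correlation between the per-channel firing-rate vectors of each
#' stimulus pair.  The matrix is symmetric with unit diagonal; stimuli
#' with zero rate variance give `NA` correlations with a warning.
#'
#' @param table rate matrix from [rate_table()] (restricted to retained
#'   channels).
#' @return stimulus x stimulus correlation matrix.
#' @export
stimulus_correlations <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 channels", call. = FALSE)
  v <- apply(table, 2, stats::var)
  if (any(v == 0))
    warning("zero-variance stimulus column(s): ",
            paste(colnames(table)[v == 0], collapse = ", "), call. = FALSE)
  suppressWarnings(cor(table))
}

#' Bundled cat visual-cortex summary tables
#'
#' `cortex_rate_table()` returns the published firing rates (Hz) of 32
#' channels recorded in cat primary visual cortex under six moving-bar
#' stimuli; channels 4, 5 and 29 are the high-rate outliers excluded from
#' the connectivity analysis.  `cortex_graph_measures()` returns the four
#' published graph measures (density, characteristic path length, global
#' efficiency, global clustering) of the six per-stimulus connectivity
#' graphs estimated from those recordings.
#'
#' @return `cortex_rate_table`: 32 x 6 numeric matrix; dimnames are
#'   channel and stimulus labels.
#' @export
cortex_rate_table <- function() {
  path <- system.file("extdata", "cortex_firing_rates_hz.csv",
                      package = "spikegraph", mustWork = TRUE)
  tab <- read.csv(path, check.names = FALSE, row.names = 1)
  as.matrix(tab)
}

#' @rdname cortex_rate_table
#' @return `cortex_graph_measures`: data frame with one row per stimulus.
#' @export
cortex_graph_measures <- function() {
  path <- system.file("extdata", "cortex_graph_measures.csv",
                      package = "spikegraph", mustWork = TRUE)
  read.csv(path)
}
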
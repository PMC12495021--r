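#' Construct a set of simultaneously recorded spike trains
#'
#' A `spike_train_set` holds, for each recording channel, a strictly
#' increasing sequence of spike times (seconds) on a common session clock,
#' together with the session duration.  Channel labels are preserved
#' verbatim through all downstream operations (dropping channels does not
#' renumber the survivors).
#'
#' @param spikes named list of numeric vectors; names are channel labels,
#'   values are spike times in seconds.  Each vector must be strictly
#'   increasing with all times in `[0, duration_s)`.
#' @param duration_s session duration in seconds.  If `NULL`, the maximum
#'   spike time is rounded up to the next integer second.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, duration_s = NULL) {
  if (!is.list(spikes) || length(spikes) == 0L)
    stop("`spikes` must be a non-empty named list of numeric vectors", call. = FALSE)
  if (is.null(names(spikes)) || anyDuplicated(names(spikes)))
    stop("channel labels must be present and unique", call. = FALSE)
  spikes <- lapply(spikes, as.numeric)
  if (is.null(duration_s)) {
    mx <- suppressWarnings(max(unlist(spikes, use.names = FALSE), 0))
    duration_s <- ceiling(mx + 1e-9)
    if (duration_s <= 0) duration_s <- 1
  }
  for (ch in names(spikes)) {
    x <- spikes[[ch]]
    if (anyNA(x)) stop("channel ", ch, ": NA spike times", call. = FALSE)
    if (length(x) && (x[1] < 0 || x[length(x)] >= duration_s))
      stop("channel ", ch, ": spike times must lie in [0, duration_s)", call. = FALSE)
    if (is.unsorted(x, strictly = TRUE))
      stop("channel ", ch, ": spike times must be strictly increasing", call. = FALSE)
  }
  structure(list(spikes = spikes, duration_s = as.numeric(duration_s)),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n <- vapply(x$spikes, length, integer(1))
  cat("<spike_train_set> ", length(n), " channels, ",
      format(x$duration_s), " s, ", sum(n), " spikes\n", sep = "")
  rate <- round(n / x$duration_s, 2)
  print(utils::head(data.frame(channel = names(n), n_spikes = as.integer(n),
                               rate_hz = rate, row.names = NULL), 10))
  if (length(n) > 10) cat("... and ", length(n) - 10, " more channels\n", sep = "")
  invisible(x)
}

#' @rdname spike_train_set
#' @param x object to test or print.
#' @export
is.spike_train_set <- function(x) inherits(x, "spike_train_set")

#' Channel labels of a spike train set
#' @param spikes a [spike_train_set()].
#' @return character vector of channel labels.
#' @export
channel_ids <- function(spikes) {
  stopifnot(is.spike_train_set(spikes))
  names(spikes$spikes)
}

#' Read a spike table
#'
#' Reads a CSV with columns `channel,time_s` into a [spike_train_set()].
#' Out-of-order times are sorted with a warning; duplicated
#' `(channel, time)` records are collapsed with a warning.
#'
#' @param path CSV file path.
#' @param duration_s session duration; if `NULL`, inferred from the data.
#' @return a [spike_train_set()].
#' @export
read_spike_table <- function(path, duration_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("channel", "time_s")
  if (!all(need %in% names(tab)))
    stop("format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L) stop("no records in ", path, call. = FALSE)
  times <- suppressWarnings(as.numeric(tab$time_s))
  bad <- which(is.na(times))
  if (length(bad))
    stop("format error: non-numeric time_s at line ", bad[1] + 1L, call. = FALSE)
  neg <- which(times < 0)
  if (length(neg))
    stop("format error: negative time_s at line ", neg[1] + 1L, call. = FALSE)
  spl <- split(times, tab$channel)
  unsorted <- any(vapply(spl, is.unsorted, logical(1)))
  if (unsorted) warning("spike times out of order; sorting", call. = FALSE)
  spl <- lapply(spl, sort)
  dup <- any(vapply(spl, anyDuplicated, numeric(1)) > 0)
  if (dup) {
    warning("duplicate (channel, time) records collapsed", call. = FALSE)
    spl <- lapply(spl, unique)
  }
  # order channels numerically when labels are numeric, else lexically
  labs <- names(spl)
  num <- suppressWarnings(as.numeric(labs))
  spl <- spl[order(if (anyNA(num)) labs else num)]
  spike_train_set(spl, duration_s)
}

#' Write a spike table
#'
#' Writes the `channel,time_s` CSV dialect read by [read_spike_table()].
#' Times are written with 6 fractional digits so that millisecond-scale
#' influence kernels survive a round trip.
#'
#' @param spikes a [spike_train_set()].
#' @param path output CSV path.
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(is.spike_train_set(spikes))
  ch <- rep(names(spikes$spikes), vapply(spikes$spikes, length, integer(1)))
  tt <- unlist(spikes$spikes, use.names = FALSE)
  df <- data.frame(channel = ch, time_s = sprintf("%.6f", tt))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a stimulus schedule
#'
#' A schedule is a table with columns
#' `stimulus_id,trial_index,start_s,end_s`: the half-open session intervals
#' `[start_s, end_s)` during which each stimulus was presented.
#'
#' @param path CSV file path.
#' @return `read_schedule`: a data frame with the four schedule columns.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.csv(path, check.names = FALSE)
  need <- c("stimulus_id", "trial_index", "start_s", "end_s")
  if (!all(need %in% names(tab)))
    stop("format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  if (any(tab$start_s >= tab$end_s))
    stop("schedule error: start_s must be < end_s", call. = FALSE)
  tab[need]
}

#' @rdname read_schedule
#' @param schedule a schedule data frame.
#' @export
write_schedule <- function(schedule, path) {
  df <- schedule[c("stimulus_id", "trial_index", "start_s", "end_s")]
  df$start_s <- sprintf("%.6f", df$start_s)
  df$end_s <- sprintf("%.6f", df$end_s)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract and concatenate the trials of one stimulus
#'
#' Selects the schedule intervals of `stimulus_id`, sorts them by start
#' time, and maps every spike falling in interval `k` at absolute time `t`
#' to `(t - start_k) + sum of earlier interval lengths`.  Spikes from the
#' trials are thereby considered on one continuous clock, ignoring the gaps
#' between trials; the output duration is the summed interval length.
#' Inter-spike intervals spanning a trial boundary are retained as-is (the
#' Cox stage can censor them instead via its `split_at` argument).
#'
#' @param spikes a [spike_train_set()] for the whole session.
#' @param schedule schedule data frame (see [read_schedule()]).
#' @param stimulus_id stimulus whose trials to extract.
#' @return a [spike_train_set()] on the concatenated clock, with attribute
#'   `"boundaries"` holding the internal concatenation boundary times.
#' @export
extract_stimulus_segments <- function(spikes, schedule, stimulus_id) {
  stopifnot(is.spike_train_set(spikes))
  sel <- schedule[schedule$stimulus_id == stimulus_id, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no schedule intervals for stimulus ", stimulus_id, call. = FALSE)
  sel <- sel[order(sel$start_s), , drop = FALSE]
  if (any(sel$start_s[-1] < sel$end_s[-nrow(sel)]))
    stop("schedule error: overlapping intervals for stimulus ", stimulus_id,
         call. = FALSE)
  len <- sel$end_s - sel$start_s
  offset <- cumsum(c(0, len[-length(len)]))  # concatenated start of interval k
  out <- lapply(spikes$spikes, function(x) {
    k <- findInterval(x, sel$start_s)         # candidate interval index
    keep <- k >= 1L & x < sel$end_s[pmax(k, 1L)]
    x[keep] - sel$start_s[k[keep]] + offset[k[keep]]
  })
  res <- spike_train_set(out, duration_s = sum(len))
  attr(res, "boundaries") <- cumsum(len)[-length(len)]
  res
}

#' Flag outlier channels by firing rate
#'
#' A channel is flagged when its rate exceeds `ceiling_hz` under any
#' stimulus, or falls below `floor_hz` under every stimulus.  With the
#' default 20 Hz ceiling (upper edge of the "medium" cortical firing-rate
#' band) this screen reproduces the exclusion of the three high-rate
#' channels in the bundled cat visual-cortex rate table.
#'
#' @param rates numeric matrix, channels x stimuli, rownames = channel
#'   labels.
#' @param ceiling_hz flag when exceeded in any stimulus (default 20).
#' @param floor_hz flag when all stimuli fall below it (default 0).
#' @return character vector of flagged channel labels.
#' @export
flag_outlier_channels <- function(rates, ceiling_hz = 20, floor_hz = 0) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (ceiling_hz <= floor_hz)
    stop("`ceiling_hz` must exceed `floor_hz`", call. = FALSE)
  hi <- apply(rates, 1, function(r) any(r > ceiling_hz))
  lo <- apply(rates, 1, function(r) all(r < floor_hz))
  rownames(rates)[hi | lo]
}

#' Drop channels from a spike train set
#'
#' Remaining channels keep their original labels.
#'
#' @param spikes a [spike_train_set()].
#' @param ids channel labels to remove.
#' @return a [spike_train_set()] without the given channels.
#' @export
drop_channels <- function(spikes, ids) {
  stopifnot(is.spike_train_set(spikes))
  ids <- as.character(ids)
  unknown <- setdiff(ids, names(spikes$spikes))
  if (length(unknown))
    stop("unknown channel id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  keep <- setdiff(names(spikes$spikes), ids)
  if (length(keep) == 0L) stop("no channels remain", call. = FALSE)
  spike_train_set(spikes$spikes[keep], spikes$duration_s)
}

#' Read / write a binary adjacency matrix
#'
#' Square CSV with a header row and a leading label column; rows are source
#' channels, columns are target channels, cells are 0/1 (column `k` lists
#' the references influencing target `k`).
#'
#' @param path CSV file path.
#' @return `read_adjacency`: 0/1 integer matrix with dimnames.
#' @export
read_adjacency <- function(path) {
  tab <- read.csv(path, check.names = FALSE, row.names = 1)
  a <- as.matrix(tab)
  if (nrow(a) != ncol(a)) stop("adjacency matrix must be square", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("adjacency cells must be 0/1", call. = FALSE)
  storage.mode(a) <- "integer"
  a
}

#' @rdname read_adjacency
#' @param a 0/1 adjacency matrix (rows = source, columns = target).
#' @export
write_adjacency <- function(a, path) {
  a <- as.matrix(a)
  df <- data.frame(a, check.names = FALSE)
  write.csv(cbind(data.frame(channel = rownames(a)), df), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
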
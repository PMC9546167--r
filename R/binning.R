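# Spike binning and module selection front-end. Event tables are long-format
# data frames with columns trial, unit, time_s, position_cm and spikes (a
# count weight per row; rows with spikes = 0 contribute nothing).

.new_binned_counts <- function(counts, bin_edges, axis, unit_ids, trial_ids) {
  structure(list(counts = counts, bin_edges = bin_edges, axis = axis,
                 unit_ids = unit_ids, trial_ids = trial_ids),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat(sprintf("<binned_counts> %d trials x %d %s bins x %d units (total %d spikes)\n",
              dim(x$counts)[1], dim(x$counts)[2], x$axis, dim(x$counts)[3],
              sum(x$counts)))
  invisible(x)
}

#' Bin spikes by corridor position
#'
#' Counts spikes per (trial, position bin, unit) with half-open bins `[a, b)`
#' and a closed last bin. Events outside the corridor are dropped with a
#' warning.
#'
#' @param events Long-format spike table with columns `trial`, `unit`,
#'   `position_cm` and `spikes`.
#' @param corridor_length_cm Corridor length (cm).
#' @param bin_cm Bin size (cm).
#' @param units,trials Optional explicit unit and trial identifiers declaring
#'   the output shape (useful for empty tables); default: those observed.
#' @return A `binned_counts` object (`trials x bins x units`).
#' @export
bin_spikes_position <- function(events, corridor_length_cm = 160, bin_cm = 20,
                                units = NULL, trials = NULL) {
  edges <- seq(0, corridor_length_cm, by = bin_cm)
  n_bins <- length(edges) - 1L
  if (is.null(trials)) trials <- sort(unique(events$trial))
  if (is.null(units)) units <- sort(unique(events$unit))
  out_of_range <- events$position_cm < 0 | events$position_cm > corridor_length_cm
  n_dropped <- sum(events$spikes[out_of_range])
  if (n_dropped > 0)
    warning(sprintf("dropped %d spikes outside the corridor", n_dropped))
  ev <- events[!out_of_range & events$spikes > 0, , drop = FALSE]
  bin <- pmin(findInterval(ev$position_cm, edges,
                           rightmost.closed = TRUE), n_bins)
  counts <- array(0L, dim = c(length(trials), n_bins, length(units)),
                  dimnames = list(trial = trials, bin = NULL, unit = units))
  ti <- match(ev$trial, trials); ui <- match(ev$unit, units)
  for (r in seq_len(nrow(ev)))
    counts[ti[r], bin[r], ui[r]] <- counts[ti[r], bin[r], ui[r]] + ev$spikes[r]
  .new_binned_counts(counts, edges, "position", units, trials)
}

#' Bin spikes in time around a per-trial event
#'
#' Counts spikes per (trial, time bin, unit) in bins tiling a symmetric window
#' around each trial's event time. With a window of 3.5 s and 0.3 s bins the
#' full 7 s span does not divide evenly; `floor(7 / 0.3) = 23` bins are used
#' and the residual is dropped symmetrically from both ends. Trials without an
#' event are excluded.
#'
#' @param events Long-format spike table with columns `trial`, `unit`,
#'   `time_s` and `spikes`.
#' @param event_times Data frame with columns `trial` and `time_s` (one event
#'   per eligible trial), or a named numeric vector keyed by trial.
#' @param window_s Half-window (s) on each side of the event.
#' @param bin_s Bin size (s).
#' @param units Optional explicit unit identifiers declaring the output shape.
#' @return A `binned_counts` object (`eligible trials x bins x units`).
#' @export
bin_spikes_event <- function(events, event_times, window_s = 3.5, bin_s = 0.3,
                             units = NULL) {
  if (is.data.frame(event_times)) {
    et <- stats::setNames(event_times$time_s, event_times$trial)
  } else et <- event_times
  n_bins <- floor(2 * window_s / bin_s)
  span <- n_bins * bin_s
  edges <- seq(-span / 2, span / 2, by = bin_s)
  trials <- sort(unique(events$trial))
  eligible <- trials[as.character(trials) %in% names(et)]
  excluded <- setdiff(trials, eligible)
  if (length(excluded) > 0)
    message(sprintf("excluded %d trials without an event", length(excluded)))
  if (length(eligible) == 0) stop("empty selection: no trial has an event")
  if (is.null(units)) units <- sort(unique(events$unit))
  counts <- array(0L, dim = c(length(eligible), n_bins, length(units)),
                  dimnames = list(trial = eligible, bin = NULL, unit = units))
  ev <- events[events$trial %in% eligible & events$spikes > 0, , drop = FALSE]
  rel <- ev$time_s - et[as.character(ev$trial)]
  keep <- rel >= edges[1] & rel < edges[length(edges)]
  ev <- ev[keep, , drop = FALSE]; rel <- rel[keep]
  bin <- findInterval(rel, edges)
  ti <- match(ev$trial, eligible); ui <- match(ev$unit, units)
  for (r in seq_len(nrow(ev)))
    counts[ti[r], bin[r], ui[r]] <- counts[ti[r], bin[r], ui[r]] + ev$spikes[r]
  .new_binned_counts(counts, edges, "time_from_event", units, eligible)
}

#' Flatten binned counts into an observation matrix
#'
#' @param bc A `binned_counts` object.
#' @param pool `"both"` treats every (trial, bin) cell as one observation;
#'   `"trial"` sums over bins (one observation per trial); `"bin"` sums over
#'   trials (one observation per bin).
#' @return An integer matrix (observations x units).
#' @export
counts_matrix <- function(bc, pool = c("both", "trial", "bin")) {
  pool <- match.arg(pool)
  dm <- dim(bc$counts)
  out <- switch(pool,
    both = matrix(aperm(bc$counts, c(2, 1, 3)), dm[1] * dm[2], dm[3]),
    trial = apply(bc$counts, c(1, 3), sum),
    bin = apply(bc$counts, c(2, 3), sum))
  colnames(out) <- bc$unit_ids
  out
}

#' Select a module of mutually rank-correlated units
#'
#' Greedily grows a subset in which every pair of units has tie-corrected
#' `|Kendall tau| > tau_threshold`, seeded at the unit with the largest total
#' absolute tau and, at each step, adding the admissible unit that maximizes
#' the minimum |tau| to the current subset. Deterministic; returns an empty
#' vector when no pair passes.
#'
#' @param counts Observation matrix (observations x units).
#' @param tau_threshold Absolute Kendall tau threshold (default 0.3).
#' @return Sorted integer indices of the selected units.
#' @export
select_module <- function(counts, tau_threshold = 0.3) {
  counts <- as.matrix(counts)
  p <- ncol(counts)
  if (p < 2) stop("need at least 2 units")
  tau <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    tij <- tryCatch(abs(kendall_tau_empirical(counts[, i], counts[, j])),
                    error = function(e) 0)
    tau[i, j] <- tau[j, i] <- tij
  }
  if (!any(tau > tau_threshold)) return(integer(0))
  seed_unit <- order(-rowSums(tau), seq_len(p))[1]
  sel <- seed_unit
  repeat {
    cand <- setdiff(seq_len(p), sel)
    ok <- cand[vapply(cand, function(cc) all(tau[cc, sel] > tau_threshold),
                      logical(1))]
    if (length(ok) == 0) break
    gain <- vapply(ok, function(cc) min(tau[cc, sel]), numeric(1))
    sel <- c(sel, ok[order(-gain, ok)[1]])
  }
  if (length(sel) < 2) return(integer(0))
  sort(sel)
}
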
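# Sleep scoring from Drosophila activity-monitor minute counts. A fly is
# scored asleep during any maximal run of >= 5 consecutive minutes without
# an activity count; immobile runs of 1-4 minutes are transient pauses
# (awake). Traits follow the standard DAM conventions: per-phase sleep
# minutes, bout numbers and average bout lengths, latency to the first
# night sleep bout, and activity counts per waking minute.

SLEEP_MIN_RUN <- 5L

#' Construct an activity trace
#'
#' @param counts non-negative per-minute activity counts; length a whole
#'   multiple of 1440 for multi-day scoring (single full days also work)
#' @param id fly identifier
#' @param lights_on_minute first minute (1-based) of the lights-on phase
#'   within each 1440-minute day; the schedule is 12h:12h, so day =
#'   minutes lights_on..lights_on+719 and night the complement
#' @return object of class \code{activity_trace}
#' @export
activity_trace <- function(counts, id = "fly", lights_on_minute = 1L) {
  if (any(counts < 0)) stop("negative activity counts", call. = FALSE)
  stopifnot(length(counts) >= 1, lights_on_minute >= 1, lights_on_minute <= 1440)
  structure(list(counts = as.numeric(counts), id = id,
                 lights_on = as.integer(lights_on_minute)),
            class = "activity_trace")
}

# per-minute phase labels for a trace: "day" during lights-on
phase_of <- function(trace) {
  m <- ((seq_along(trace$counts) - trace$lights_on) %% 1440)
  ifelse(m < 720, "day", "night")
}

#' Classify each minute as sleep, wake or transient pause
#'
#' @param trace an \code{activity_trace} (or bare counts vector)
#' @return character vector, per minute, in {"sleep", "wake", "pause"}
#' @export
classify_states <- function(trace) {
  counts <- if (inherits(trace, "activity_trace")) trace$counts else trace
  if (length(counts) == 0) stop("empty trace", call. = FALSE)
  if (any(counts < 0)) stop("negative activity counts", call. = FALSE)
  immobile <- counts == 0
  r <- rle(immobile)
  lab <- ifelse(!r$values, "wake",
                ifelse(r$lengths >= SLEEP_MIN_RUN, "sleep", "pause"))
  rep(lab, r$lengths)
}

# bout table: one row per maximal sleep run, with onset phase attribution
sleep_bouts <- function(states, phase) {
  r <- rle(states == "sleep")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep],
             onset_phase = phase[starts[keep]])
}

#' Score sleep traits for one fly
#'
#' Phase sleep totals count sleep-labelled minutes inside each phase; a
#' bout spanning a lights transition is one bout, attributed (number and
#' bout-length accounting) to the phase in which it began. Latency is the
#' number of minutes from each lights-off to the first sleep-labelled
#' minute of that night (720 if the fly never sleeps that night; 0 when
#' already asleep at lights-off). Waking activity is total counts divided
#' by wake-labelled minutes. Multi-day traces are scored per day and
#' averaged.
#'
#' @param trace an \code{activity_trace} covering >= 1 full day
#' @param discard_first_day drop day 1 before scoring (acclimation)
#' @return one-row data.frame with night_sleep, day_sleep,
#'   night_bout_number, day_bout_number, night_avg_bout_length,
#'   day_avg_bout_length, sleep_latency, waking_activity
#' @export
score_traits <- function(trace, discard_first_day = FALSE) {
  per_day <- score_days(trace, discard_first_day)
  out <- as.data.frame(t(colMeans(per_day[, -1L, drop = FALSE], na.rm = TRUE)))
  out$waking_activity[is.nan(out$waking_activity)] <- NA_real_
  out
}

#' Per-day sleep traits
#'
#' @inheritParams score_traits
#' @return data.frame with a day column and the eight traits per day
#' @export
score_days <- function(trace, discard_first_day = FALSE) {
  stopifnot(inherits(trace, "activity_trace"))
  n <- length(trace$counts)
  if (n < 1440) stop("trace must cover at least one full day", call. = FALSE)
  n_days <- n %/% 1440
  states <- classify_states(trace)
  phase <- phase_of(trace)
  day_idx <- (seq_len(n) - 1L) %/% 1440 + 1L
  bouts <- sleep_bouts(states, phase)
  bout_day <- (bouts$start - 1L) %/% 1440 + 1L

  first_day <- if (discard_first_day) 2L else 1L
  if (n_days < first_day) stop("no full day left after discarding day 1",
                               call. = FALSE)
  rows <- lapply(first_day:n_days, function(d) {
    in_d <- day_idx == d & seq_len(n) <= n_days * 1440
    st <- states[in_d]; ph <- phase[in_d]; ct <- trace$counts[in_d]
    b <- bouts[bout_day == d, , drop = FALSE]
    night_b <- b[b$onset_phase == "night", , drop = FALSE]
    day_b <- b[b$onset_phase == "day", , drop = FALSE]
    # latency: minutes from this day's lights-off to first night sleep minute
    night_pos <- which(ph == "night")
    night_states <- st[night_pos]
    lat <- if (any(night_states == "sleep")) which(night_states == "sleep")[1L] - 1L
           else 720
    wake_min <- sum(st == "wake" | st == "pause")
    data.frame(
      day = d,
      night_sleep = sum(st == "sleep" & ph == "night"),
      day_sleep = sum(st == "sleep" & ph == "day"),
      night_bout_number = nrow(night_b),
      day_bout_number = nrow(day_b),
      night_avg_bout_length = if (nrow(night_b)) mean(night_b$length) else 0,
      day_avg_bout_length = if (nrow(day_b)) mean(day_b$length) else 0,
      sleep_latency = lat,
      waking_activity = if (wake_min > 0) sum(ct) / wake_min else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Per-minute behavioural state fractions across a population
#'
#' @param states list of per-minute state vectors (equal length, aligned)
#' @return data.frame minute, sleep, wake, pause fractions (sum to 1)
#' @export
population_state_fractions <- function(states) {
  if (length(states) == 0) stop("empty collection", call. = FALSE)
  len <- unique(vapply(states, length, 0L))
  if (length(len) != 1L) stop("traces not aligned", call. = FALSE)
  M <- do.call(rbind, states)
  data.frame(
    minute = seq_len(len),
    sleep = colMeans(M == "sleep"),
    wake = colMeans(M == "wake"),
    pause = colMeans(M == "pause")
  )
}

#' Sleep-deprivation response deltas
#'
#' @param day_traits data.frame from \code{\link{score_days}} (columns day,
#'   night_sleep, day_sleep at minimum)
#' @param baseline_days day indices averaged into the baseline
#' @param event_day deprivation day
#' @param recovery_day recovery day
#' @return data.frame with rows event/recovery and columns night_delta,
#'   day_delta, total_delta, night_pct, day_pct, total_pct (percent change
#'   vs baseline; NA when the baseline is zero)
#' @export
deprivation_deltas <- function(day_traits, baseline_days, event_day,
                               recovery_day) {
  stopifnot(length(baseline_days) >= 1, all(baseline_days < event_day))
  need <- c(baseline_days, event_day, recovery_day)
  if (!all(need %in% day_traits$day)) stop("missing day", call. = FALSE)
  base <- day_traits[day_traits$day %in% baseline_days, , drop = FALSE]
  b_night <- mean(base$night_sleep)
  b_day <- mean(base$day_sleep)
  b_tot <- b_night + b_day
  one <- function(d) {
    r <- day_traits[day_traits$day == d, , drop = FALSE]
    tot <- r$night_sleep + r$day_sleep
    data.frame(
      night_delta = r$night_sleep - b_night, day_delta = r$day_sleep - b_day,
      total_delta = tot - b_tot,
      night_pct = if (b_night != 0) 100 * (r$night_sleep - b_night) / b_night else NA_real_,
      day_pct = if (b_day != 0) 100 * (r$day_sleep - b_day) / b_day else NA_real_,
      total_pct = if (b_tot != 0) 100 * (tot - b_tot) / b_tot else NA_real_
    )
  }
  out <- rbind(one(event_day), one(recovery_day))
  rownames(out) <- c("event", "recovery")
  out
}

#' Flag flies that likely died during recording
#'
#' @param trace an \code{activity_trace}
#' @param terminal_immobility_min minutes of terminal immobility that flag
#'   a death (default one full day)
#' @return TRUE when the trailing immobile span reaches the threshold
#' @export
flag_dead <- function(trace, terminal_immobility_min = 1440L) {
  counts <- trace$counts
  r <- rle(counts == 0)
  k <- length(r$values)
  k > 0 && r$values[k] && r$lengths[k] >= terminal_immobility_min
}

#' Read a DAM-style tab-delimited monitor file
#'
#' One row per minute, one column per monitor channel, tab separated; a
#' leading minute-index column is tolerated and dropped when detected.
#'
#' @param path file path
#' @param lights_on_minute passed to \code{\link{activity_trace}}
#' @return named list of \code{activity_trace}, one per channel
#' @export
read_dam <- function(path, lights_on_minute = 1L) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  if (ncol(m) > 1 && all(diff(m[, 1L]) == 1)) m <- m[, -1L, drop = FALSE]
  lapply(stats::setNames(seq_len(ncol(m)),
                         paste0("ch", seq_len(ncol(m)))),
         function(j) activity_trace(m[, j], id = paste0("ch", j),
                                    lights_on_minute = lights_on_minute))
}

#' Write activity traces as a DAM-style tab-delimited file
#'
#' @param traces list of \code{activity_trace} of equal length
#' @param path output path
#' @export
write_dam <- function(traces, path) {
  m <- cbind(seq_along(traces[[1L]]$counts),
             do.call(cbind, lapply(traces, `[[`, "counts")))
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
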
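# Cut-event detection on acceleration traces, per-cut representative angles,
# and the three-band ergonomic risk classification with frequency reporting.

RISK_LEVELS <- c("low", "medium", "high")

#' Risk band thresholds
#'
#' Default bands follow the simplified upper-limb posture limits used in
#' checklist methods (RULA-style): low (acceptable) up to 20 degrees, medium
#' (monitor) up to 45 degrees, high (unacceptable) beyond.
#'
#' @param low_max Upper limit of the low band in degrees, inclusive.
#' @param med_max Upper limit of the medium band in degrees, inclusive; 45
#'   degrees itself is still medium, anything strictly above is high.
#' @return A list of class `risk_thresholds`.
#' @export
risk_thresholds <- function(low_max = 20, med_max = 45) {
  if (!is.numeric(low_max) || !is.numeric(med_max) ||
      !(0 < low_max && low_max < med_max))
    vw_config_error("thresholds must satisfy 0 < low_max < med_max")
  structure(list(low_max = low_max, med_max = med_max),
            class = "risk_thresholds")
}

#' Classify wrist angles into risk bands
#'
#' Classification is on the absolute angle: `|angle|` in `[0, low_max]` is
#' low, `(low_max, med_max]` medium, above `med_max` high.
#'
#' @param angle Numeric vector of angles in degrees (sign ignored).
#' @param thresholds A [risk_thresholds()].
#' @return An ordered factor with levels `low < medium < high`.
#' @export
classify_angle <- function(angle, thresholds = risk_thresholds()) {
  if (!is.numeric(angle) || length(angle) == 0L || any(!is.finite(angle)))
    vw_validation_error("angles must be finite numeric")
  a <- abs(angle)
  lev <- ifelse(a <= thresholds$low_max, "low",
                ifelse(a <= thresholds$med_max, "medium", "high"))
  factor(lev, levels = RISK_LEVELS, ordered = TRUE)
}

#' Detect cut events on an acceleration trace
#'
#' Automated replacement for graphical inspection of the hand-sensor
#' acceleration trace: cut events are bursts where the acceleration magnitude
#' deviates from gravity by more than `threshold`. Bursts closer than
#' `min_gap` are merged; when `expected_count` is given, the strongest k
#' bursts are returned in time order (with a warning if fewer are found).
#'
#' @param stream An [imu_stream()] (typically S2, the hand sensor).
#' @param threshold Excess over gravity in m/s^2 that marks a burst
#'   (default 2).
#' @param min_gap Minimum separation between distinct events in seconds
#'   (default 0.5).
#' @param expected_count Optional number of cuts the protocol prescribes.
#' @param gravity_mag Gravity magnitude, m/s^2.
#' @return A data frame of class `cut_events` with columns
#'   `start, end, peak_t, peak_excess` (seconds, m/s^2); zero rows when the
#'   trace never exceeds the threshold.
#' @export
detect_cut_windows <- function(stream, threshold = 2, min_gap = 0.5,
                               expected_count = NULL, gravity_mag = 9.81) {
  t <- stream$t
  if (t[length(t)] - t[1] <= min_gap)
    vw_validation_error("stream shorter than min_gap")
  excess <- abs(sqrt(rowSums(stream_accel(stream)^2)) - gravity_mag)
  above <- excess > threshold
  ev <- data.frame(start = numeric(0), end = numeric(0),
                   peak_t = numeric(0), peak_excess = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
    # merge runs separated by less than min_gap
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1L) for (j in 2:nrow(runs)) {
      if (t[runs$i0[j]] - t[merged$i1[nrow(merged)]] < min_gap)
        merged$i1[nrow(merged)] <- runs$i1[j]
      else merged <- rbind(merged, runs[j, ])
    }
    ev <- do.call(rbind, lapply(seq_len(nrow(merged)), function(j) {
      idx <- merged$i0[j]:merged$i1[j]
      k <- idx[which.max(excess[idx])]
      data.frame(start = t[merged$i0[j]], end = t[merged$i1[j]],
                 peak_t = t[k], peak_excess = excess[k])
    }))
  }
  if (!is.null(expected_count)) {
    if (nrow(ev) < expected_count)
      warning(sprintf("expected %d cut bursts but detected only %d",
                      expected_count, nrow(ev)), call. = FALSE)
    if (nrow(ev) > expected_count) {
      keep <- order(ev$peak_excess, decreasing = TRUE)[seq_len(expected_count)]
      ev <- ev[sort(keep), ]
    }
  }
  rownames(ev) <- NULL
  structure(ev, class = c("cut_events", "data.frame"))
}

#' Representative angle of a cut window
#'
#' Per axis, the signed angle of maximal absolute value inside the window
#' (risk methods score the worst posture reached).
#'
#' @param angles A `joint_angle_series` (see [wrist_angles()]).
#' @param window A list or one-row data frame with `start` and `end` seconds.
#' @return Named vector `c(x=, y=, z=)` in degrees, signs preserved.
#' @export
representative_angle <- function(angles, window) {
  sel <- angles$t >= window$start & angles$t <= window$end
  if (!any(sel)) vw_validation_error("window contains no samples")
  vapply(c("x", "y", "z"), function(ax) {
    v <- angles[[ax]][sel]
    v[which.max(abs(v))]
  }, numeric(1))
}

#' Representative angles for a set of cut events
#'
#' @param angles A `joint_angle_series`.
#' @param events A `cut_events` data frame.
#' @return Data frame with one row per event: `start, end, x, y, z`.
#' @export
representative_angles <- function(angles, events) {
  reps <- t(vapply(seq_len(nrow(events)), function(j)
    representative_angle(angles, events[j, ]), numeric(3)))
  data.frame(start = events$start, end = events$end,
             x = reps[, 1], y = reps[, 2], z = reps[, 3])
}

#' Frequency of risk bands per axis
#'
#' Counts angle records per axis and band and reports truncated (floor)
#' integer percentages, per axis and pooled over all axes.
#'
#' @param records Data frame with columns `axis` (`"X"`, `"Y"`, `"Z"`) and
#'   `angle_deg`.
#' @param thresholds A [risk_thresholds()].
#' @return A list of class `risk_report`: `counts` and `pct` (4 rows X, Y, Z,
#'   All by 3 bands), `n` per row, `thresholds`.
#' @export
risk_frequency_table <- function(records, thresholds = risk_thresholds()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    vw_validation_error("no angle records supplied")
  if (!all(c("axis", "angle_deg") %in% names(records)))
    vw_validation_error("records need columns 'axis' and 'angle_deg'")
  axes <- toupper(as.character(records$axis))
  if (!all(axes %in% c("X", "Y", "Z")))
    vw_validation_error("axis must be one of X, Y, Z")
  band <- classify_angle(records$angle_deg, thresholds)
  rows <- c("X", "Y", "Z", "All")
  counts <- matrix(0L, 4, 3, dimnames = list(rows, RISK_LEVELS))
  for (ax in c("X", "Y", "Z"))
    counts[ax, ] <- as.integer(table(band[axes == ax]))
  counts["All", ] <- as.integer(table(band))
  n <- rowSums(counts)
  pct <- floor(100 * counts / n)
  structure(list(counts = counts, pct = pct, n = n, thresholds = thresholds),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  th <- x$thresholds
  bands <- c(sprintf("0-%g", th$low_max),
             sprintf("%g-%g", th$low_max, th$med_max),
             sprintf(">%g", th$med_max))
  cat("Risk-band frequency (% of angle records, truncated)\n")
  for (k in 3:1) {
    cat(sprintf("%-7s %-6s", RISK_LEVELS[k], bands[k]))
    for (ax in c("X", "Y", "Z", "All"))
      cat(sprintf("  %s %3d%%", ax, x$pct[ax, RISK_LEVELS[k]]))
    cat("\n")
  }
  invisible(x)
}

#' Tabular forms of a risk report
#'
#' `risk_report_csv()` mirrors the published table layout
#' (`level, band, X, Y, Z, All` in percent); `risk_report_json()` carries the
#' raw counts.
#'
#' @param report A `risk_report`.
#' @return A data frame / JSON string.
#' @export
risk_report_csv <- function(report) {
  th <- report$thresholds
  bands <- c(sprintf("0-%g", th$low_max),
             sprintf("%g-%g", th$low_max, th$med_max),
             sprintf(">%g", th$med_max))
  data.frame(level = RISK_LEVELS[3:1], band = bands[3:1],
             X = report$pct[1, 3:1], Y = report$pct[2, 3:1],
             Z = report$pct[3, 3:1], All = report$pct[4, 3:1],
             row.names = NULL)
}

#' @rdname risk_report_csv
#' @export
risk_report_json <- function(report) {
  jsonlite::toJSON(list(counts = as.data.frame.table(report$counts,
                                                     responseName = "count"),
                        n = as.list(report$n),
                        thresholds = unclass(report$thresholds)),
                   auto_unbox = TRUE, digits = NA)
}
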
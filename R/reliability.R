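# Reference-angle validation statistics: per-condition means and sample
# standard deviations of the laboratory trials, plus fixture loaders for the
# published measurement tables.

#' Load the reference-angle trial fixture
#'
#' The laboratory validation protocol: four right-handed operators moved the
#' instrumented wrist to reference postures of 15, 45 and 60 degrees on each
#' cardinal axis, three repetitions each, giving 108 measured angles.
#'
#' @param path Optional path to a CSV with columns
#'   `operator,axis,reference_angle,repetition,measured_angle`; defaults to
#'   the fixture shipped with the package.
#' @return A data frame of class `reference_trials` (one row per trial).
#' @export
load_reference_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_angle_trials.csv",
                                package = "vinewrist", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("operator", "axis", "reference_angle", "repetition", "measured_angle")
  if (!all(need %in% names(d)))
    vw_structural_error(sprintf("reference fixture needs columns: %s",
                                paste(need, collapse = ", ")))
  if (!all(d$reference_angle %in% c(15, 45, 60)))
    vw_validation_error("reference_angle outside the protocol set {15, 45, 60}")
  if (!all(toupper(d$axis) %in% c("X", "Y", "Z")))
    vw_validation_error("axis must be one of X, Y, Z")
  d$axis <- toupper(d$axis)
  structure(d, class = c("reference_trials", "data.frame"))
}

#' Load the pruning-trial angle fixture
#'
#' Wrist angles estimated for four operators over three sequences of seven
#' cuts each on the experimental vine (252 angle records: 84 per axis).
#'
#' @param path Optional CSV path with columns
#'   `operator,sequence,cut,axis,angle_deg`; defaults to the shipped fixture.
#' @return A data frame (one row per operator x sequence x cut x axis).
#' @export
load_pruning_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pruning_cut_angles.csv",
                                package = "vinewrist", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("operator", "sequence", "cut", "axis", "angle_deg")
  if (!all(need %in% names(d)))
    vw_structural_error(sprintf("pruning fixture needs columns: %s",
                                paste(need, collapse = ", ")))
  d$axis <- toupper(d$axis)
  d
}

#' Summarize reference-angle trials
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' measured angles per (reference angle x axis) cell, plus a pooled `All`
#' column per reference angle that aggregates the raw values of all three
#' axes. Values are kept at full precision; use [format_reference_summary()]
#' for the 2-decimal reporting form.
#'
#' @param trials A data frame as returned by [load_reference_fixture()].
#' @return A data frame of class `reference_summary` with columns
#'   `reference_angle, axis, n, mean, sd` (axis `"All"` rows are the pooled
#'   cells). Cells with a single trial get `sd = NA` with a warning.
#' @export
summarize_reference_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    vw_validation_error("no trials supplied")
  cell <- function(values, angle, axis) {
    if (length(values) < 2L) {
      warning(sprintf("cell (%g, %s) has n = %d < 2: SD omitted",
                      angle, axis, length(values)), call. = FALSE)
      s <- NA_real_
    } else s <- stats::sd(values)
    data.frame(reference_angle = angle, axis = axis, n = length(values),
               mean = mean(values), sd = s)
  }
  angles <- sort(unique(trials$reference_angle))
  out <- do.call(rbind, lapply(angles, function(ang) {
    sub <- trials[trials$reference_angle == ang, ]
    rows <- lapply(intersect(c("X", "Y", "Z"), unique(sub$axis)), function(ax)
      cell(sub$measured_angle[sub$axis == ax], ang, ax))
    rbind(do.call(rbind, rows), cell(sub$measured_angle, ang, "All"))
  }))
  rownames(out) <- NULL
  structure(out, class = c("reference_summary", "data.frame"))
}

#' Reporting form of a reference summary
#'
#' Rounds means and SDs to two decimals (round-half-even, the default of
#' [round()]) at the output boundary only.
#'
#' @param summary A `reference_summary`.
#' @return A data frame with `mean` and `sd` rounded and a `label` column
#'   `"mean +- sd"`.
#' @export
format_reference_summary <- function(summary) {
  out <- as.data.frame(summary)
  out$mean <- round(out$mean, 2)
  out$sd <- round(out$sd, 2)
  out$label <- ifelse(is.na(out$sd), sprintf("%.2f", out$mean),
                      sprintf("%.2f ± %.2f", out$mean, out$sd))
  out
}

#' @export
print.reference_summary <- function(x, ...) {
  print.data.frame(format_reference_summary(x))
  invisible(x)
}

#' Convenience mixed-model fit of the reference trials
#'
#' A clearly-labelled delegate to `nlme::lme` fitting measured angle on
#' reference angle, axis and their interaction, with operator and
#' repetition-in-operator random effects and an AR(1) within-operator
#' correlation. This is an off-the-shelf fit offered for exploration only; no
#' numerical claims are attached to it and nothing else in the package
#' depends on it.
#'
#' @param trials A data frame as returned by [load_reference_fixture()].
#' @return The fitted `lme` object.
#' @export
fit_reference_model <- function(trials) {
  if (!requireNamespace("nlme", quietly = TRUE))
    vw_structural_error("fit_reference_model requires the 'nlme' package")
  d <- trials
  d$reference_angle <- factor(d$reference_angle)
  d$axis <- factor(d$axis)
  d$operator <- factor(d$operator)
  nlme::lme(measured_angle ~ reference_angle * axis,
            random = ~ 1 | operator / repetition,
            correlation = nlme::corAR1(),
            data = d)
}
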
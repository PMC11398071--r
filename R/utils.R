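# internal helpers shared across modules

SENSOR_IDS <- c("S1", "S2", "S3")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vw_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "vw_error", "error"), call = call))
}

vw_parse_error      <- function(msg) vw_stop(msg, "vw_parse_error")
vw_validation_error <- function(msg) vw_stop(msg, "vw_validation_error")
vw_structural_error <- function(msg) vw_stop(msg, "vw_structural_error")
vw_config_error     <- function(msg) vw_stop(msg, "vw_config_error")

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    vw_validation_error(sprintf("%s must be finite numeric", what))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cumulative trapezoidal integral of y over t, same length as t, starts at 0
cumtrapz1 <- function(t, y) {
  n <- length(t)
  if (n < 2) return(rep(0, n))
  dt <- diff(t)
  c(0, cumsum(0.5 * (y[-n] + y[-1]) * dt))
}

# distance (degrees) from theta to the nearest odd multiple of 90 degrees
gimbal_distance <- function(theta_y) {
  abs(((theta_y %% 180) + 180) %% 180 - 90)
}
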
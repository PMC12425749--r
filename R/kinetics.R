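#' Default kinetic parameter sets
#'
#' FDG-like rate constants (1/min) for the four phantom regions and a
#' Feng-style tri-exponential arterial input function. The absolute
#' values are implementer-chosen defaults in the range reported for FDG
#' brain studies, with the lesion the hottest region; every value can
#' be overridden.
#'
#' @return Named list: per-region lists with `K1`, `k2`, `k3`, `k4`
#'   (1/min) and `fv` (blood-volume fraction, unitless).
#' @export
default_kinetics <- function() {
  list(
    background = list(K1 = 0.020, k2 = 0.150, k3 = 0.010, k4 = 0.0040, fv = 0),
    gray       = list(K1 = 0.102, k2 = 0.130, k3 = 0.062, k4 = 0.0068, fv = 0),
    white      = list(K1 = 0.054, k2 = 0.109, k3 = 0.045, k4 = 0.0058, fv = 0),
    lesion     = list(K1 = 0.150, k2 = 0.120, k3 = 0.082, k4 = 0.0068, fv = 0)
  )
}

#' Default input-function parameters (Feng tri-exponential)
#'
#' Plasma curve `Cp(t) = (A1*t - A2 - A3) e^{-l1 t} + A2 e^{-l2 t} + A3 e^{-l3 t}`
#' with `Cp(0) = 0`. Amplitudes in arbitrary activity units, decay
#' rates in 1/min.
#'
#' @export
default_input_params <- function() {
  list(A1 = 851.1, A2 = 21.88, A3 = 20.81,
       l1 = 4.134, l2 = 0.1191, l3 = 0.0104)
}

#' Evaluate the arterial input function
#'
#' Feng-style tri-exponential bolus model. A single-exponential bolus
#' `A t e^{-lambda t}` is the special case `A1 = A`, `A2 = A3 = 0`,
#' `l1 = lambda`.
#'
#' @param times Sample times in minutes (nondecreasing, >= 0).
#' @param params List with `A1`, `A2`, `A3` (amplitudes) and
#'   `l1`, `l2`, `l3` (decay rates, 1/min).
#' @return Nonnegative plasma activity at `times`; zero at t = 0.
#' @export
input_function <- function(times, params = default_input_params()) {
  if (any(times < 0)) stop("negative times are not allowed")
  if (is.unsorted(times)) stop("'times' must be nondecreasing")
  p <- params
  cp <- (p$A1 * times - p$A2 - p$A3) * exp(-p$l1 * times) +
    p$A2 * exp(-p$l2 * times) + p$A3 * exp(-p$l3 * times)
  pmax(cp, 0)
}

#' Solve the two-tissue (three-compartment) model for a tissue TAC
#'
#' Compartments: plasma Cp (forcing), free tissue C1, bound tissue C2:
#' \deqn{dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2, \quad dC2/dt = k3 C1 - k4 C2.}
#' The returned time-activity curve is total tissue activity
#' `(1 - fv)(C1 + C2) + fv * Cp`.
#'
#' The ODE system is integrated with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, rtol 1e-8); the plasma forcing is interpolated
#' linearly from a dense internal grid.
#'
#' @param params List with rate constants `K1`, `k2`, `k3`, `k4`
#'   (1/min, all >= 0) and blood-volume fraction `fv`.
#' @param input_curve Function of time (minutes) returning plasma
#'   activity, or a list with `times`/`values` to interpolate.
#' @param times Output times in minutes (nondecreasing, >= 0).
#' @return Nonnegative tissue TAC at `times`.
#' @export
solve_tissue_tac <- function(params, input_curve, times) {
  if (any(times < 0)) stop("negative times are not allowed")
  rates <- unlist(params[c("K1", "k2", "k3", "k4")])
  if (any(rates < 0)) stop("rate constants must be nonnegative")
  fv <- if (is.null(params$fv)) 0 else params$fv

  cp_fun <- if (is.function(input_curve)) {
    input_curve
  } else {
    stats::approxfun(input_curve$times, input_curve$values, rule = 2)
  }

  if (params$K1 == 0) {
    tac <- rep(0, length(times)) + fv * cp_fun(times)
    return(pmax(tac, 0))
  }

  deriv <- function(t, y, parms) {
    cp <- cp_fun(t)
    d1 <- parms$K1 * cp - (parms$k2 + parms$k3) * y[1] + parms$k4 * y[2]
    d2 <- parms$k3 * y[1] - parms$k4 * y[2]
    list(c(d1, d2))
  }
  tmax <- max(times)
  # dense grid so lsoda sees the sharp bolus; union with requested times
  grid <- sort(unique(c(0, times, seq(0, tmax, length.out = max(200L, ceiling(tmax * 20)) + 1L))))
  sol <- deSolve::lsoda(y = c(C1 = 0, C2 = 0), times = grid, func = deriv,
                        parms = params, rtol = 1e-8, atol = 1e-10)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE integrator failed to converge for the compartment model")
  keep <- match(times, sol[, "time"])
  tissue <- sol[keep, "C1"] + sol[keep, "C2"]
  pmax((1 - fv) * tissue + fv * cp_fun(times), 0)
}

#' Dynamic frame schedule
#'
#' Defaults to the 24-frame, 60-minute protocol
#' 4 x 20 s, 4 x 40 s, 4 x 60 s, 4 x 180 s, 8 x 300 s.
#'
#' @param durations Frame durations in seconds (all > 0).
#' @return Object of class `frame_schedule`: list with `start`, `dur`
#'   (seconds), `n_frames`, `total`.
#' @export
frame_schedule <- function(durations = c(rep(20, 4), rep(40, 4), rep(60, 4),
                                         rep(180, 4), rep(300, 8))) {
  if (any(durations <= 0)) stop("frame durations must be positive")
  starts <- cumsum(c(0, durations[-length(durations)]))
  structure(list(start = starts, dur = durations,
                 n_frames = length(durations), total = sum(durations)),
            class = "frame_schedule")
}

#' Time-average a TAC over each frame of a schedule
#'
#' Each frame value is the mean of the curve over the frame interval
#' (count integration over the frame duration divided by the duration),
#' computed by trapezoidal quadrature on a dense sub-grid.
#'
#' @param tac Function of time in minutes, or list with `times` (min)
#'   and `values` to interpolate linearly.
#' @param schedule A `frame_schedule` (seconds).
#' @param n_sub Number of quadrature sub-intervals per frame.
#' @return Numeric vector, one mean activity per frame.
#' @export
frame_integrate <- function(tac, schedule, n_sub = 50L) {
  stopifnot(inherits(schedule, "frame_schedule"))
  f <- if (is.function(tac)) {
    tac
  } else {
    if (max(tac$times) * 60 < schedule$total - 1e-9)
      stop("schedule extends beyond the support of the supplied TAC")
    stats::approxfun(tac$times, tac$values, rule = 2)
  }
  vapply(seq_len(schedule$n_frames), function(j) {
    t0 <- schedule$start[j] / 60
    t1 <- (schedule$start[j] + schedule$dur[j]) / 60
    tt <- seq(t0, t1, length.out = n_sub + 1L)
    vals <- f(tt)
    sum((vals[-1] + vals[-length(vals)]) / 2 * diff(tt)) / (t1 - t0)
  }, numeric(1))
}

#' Populate the phantom with per-region frame activities
#'
#' @param phantom A `pet_phantom`.
#' @param region_frames Named list (one entry per region name present
#'   in the phantom) of per-frame mean activities, all the same length.
#' @return Matrix of ground-truth dynamic activity, side^2 pixels
#'   (column-major) x frames.
#' @export
build_activity_frames <- function(phantom, region_frames) {
  stopifnot(inherits(phantom, "pet_phantom"))
  lab <- as.vector(phantom$label_grid)
  present <- phantom$region_names[as.character(sort(unique(lab)))]
  missing <- setdiff(present, names(region_frames))
  if (length(missing))
    stop("missing frame activities for region(s): ", paste(missing, collapse = ", "))
  nf <- unique(vapply(region_frames[present], length, integer(1)))
  if (length(nf) != 1L)
    stop("all regional frame-activity vectors must have equal length")
  out <- matrix(0, length(lab), nf)
  for (code in sort(unique(lab))) {
    nm <- phantom$region_names[as.character(code)]
    out[lab == code, ] <- matrix(region_frames[[nm]], sum(lab == code), nf,
                                 byrow = TRUE)
  }
  if (any(out < 0)) stop("activities must be nonnegative")
  out
}
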
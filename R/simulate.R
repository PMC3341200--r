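# Integration services: piecewise-constant input schedules, trajectory
# simulation (compiled RHS via deSolve by default) and steady-state
# location by long integration.

#' Piecewise-constant input schedule for ERKp and JAKp
#'
#' The two pathway inputs are constants between breakpoints; a signalling
#' event ("activation") is a step in one or both levels.  At a breakpoint
#' the new level applies from that instant on.
#'
#' @param time Strictly increasing breakpoint times (minutes); the first
#'   must be 0.
#' @param erkp,jakp Non-negative input levels (au), one per breakpoint.
#' @return Data frame with columns `time`, `ERKp`, `JAKp`, class
#'   `"pias3net_schedule"`.
#' @examples
#' # resting inputs for 2880 min, then a step to full activation
#' input_schedule(c(0, 2880), erkp = c(10, 1000), jakp = c(10, 1000))
#' @export
input_schedule <- function(time, erkp, jakp) {
  stopifnot(length(time) == length(erkp), length(time) == length(jakp))
  if (time[1] != 0) stop("schedule must start at time 0", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  if (any(erkp < 0) || any(jakp < 0)) {
    stop("input levels must be non-negative", call. = FALSE)
  }
  structure(data.frame(time = time, ERKp = erkp, JAKp = jakp),
            class = c("pias3net_schedule", "data.frame"))
}

# Parameter vector handed to the integrator: 30 core constants plus the
# segment's constant inputs.
solver_parms <- function(params, erkp, jakp) {
  c(as.numeric(params[core_parameter_names()]), erkp, jakp)
}

# One constant-input integration leg.  Returns the deSolve output matrix.
integrate_segment <- function(state, times, params, erkp, jakp,
                              atol, rtol, engine) {
  if (engine == "compiled") {
    out <- deSolve::ode(
      y = as.numeric(state[state_names()]), times = times,
      func = "pias3net_derivs", parms = solver_parms(params, erkp, jakp),
      dllname = "pias3net", initfunc = "pias3net_initmod",
      atol = atol, rtol = rtol, method = "lsoda")
  } else {
    fn <- function(t, y, parms) {
      names(y) <- state_names()
      list(as.numeric(model_rhs(t, y, params, erkp, jakp)))
    }
    out <- deSolve::ode(
      y = as.numeric(state[state_names()]), times = times, func = fn,
      parms = NULL, atol = atol, rtol = rtol, method = "lsoda")
  }
  if (attr(out, "istate")[1] < 0) {
    stop(sprintf(
      "ODE solver failed (istate %d) on segment [%g, %g] min, ERKp=%g, JAKp=%g",
      attr(out, "istate")[1], times[1], times[length(times)], erkp, jakp),
      call. = FALSE)
  }
  out
}

#' Simulate the model over a time horizon
#'
#' Integrates the mass-action system with the stiff-capable `lsoda`
#' solver, phase by phase over the input schedule.  Reported states are
#' floored at zero (and `R` clamped to `[0, 1]`) to absorb solver
#' round-off; amounts more negative than `1e-4` au raise an error rather
#' than being hidden.
#'
#' @param params Parameter vector from [default_parameters()], possibly
#'   with overrides.
#' @param initial Named initial state; defaults to [empty_state()].
#' @param duration Simulation horizon (minutes, > 0).
#' @param schedule Optional [input_schedule()]; if absent, `erkp` and
#'   `jakp` are held constant.
#' @param erkp,jakp Constant input levels used when no schedule is given;
#'   default to the baselines in `params`.
#' @param report_step Reporting interval (minutes) when `times` is not
#'   given.
#' @param times Explicit reporting times (minutes, starting at 0);
#'   overrides `report_step`.
#' @param atol,rtol Absolute (au) and relative integration tolerances.
#' @param engine `"compiled"` (C right-hand side; default) or `"r"`
#'   (reference implementation [model_rhs()]).
#' @return A `"pias3net_trajectory"`: data frame with `time_min`, the 15
#'   state variables, the applied `ERKp`/`JAKp`, and the two activity
#'   readouts `MITF_activity` and `STAT3_activity`.  Provenance
#'   (parameters, solver settings) is attached as attributes.
#' @export
simulate_model <- function(params = default_parameters(), initial = NULL,
                           duration, schedule = NULL,
                           erkp = params[["ERKp_baseline"]],
                           jakp = params[["JAKp_baseline"]],
                           report_step = 1, times = NULL,
                           atol = 1e-8, rtol = 1e-6,
                           engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  validate_parameters(params)
  if (is.null(initial)) initial <- empty_state(params)
  validate_state(initial)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)

  if (is.null(times)) {
    times <- unique(c(seq(0, duration, by = report_step), duration))
  }
  times <- sort(unique(times))
  if (times[1] != 0) times <- c(0, times)
  if (max(times) > duration) stop("reporting times exceed duration", call. = FALSE)

  if (is.null(schedule)) {
    schedule <- input_schedule(0, erkp, jakp)
  }
  breaks <- schedule$time[schedule$time < duration]
  seg_start <- breaks
  seg_end <- c(breaks[-1], duration)

  state <- initial
  rows <- vector("list", length(seg_start))
  inputs <- vector("list", length(seg_start))
  for (k in seq_along(seg_start)) {
    a <- seg_start[k]; b <- seg_end[k]
    seg_times <- unique(c(a, times[times > a & times < b], b))
    ek <- schedule$ERKp[k]; jk <- schedule$JAKp[k]
    out <- integrate_segment(state, seg_times, params, ek, jk,
                             atol, rtol, engine)
    state <- stats::setNames(as.numeric(out[nrow(out), -1]), state_names())
    # tidy round-off on the carried state so the next leg starts admissible
    state[state < 0] <- 0
    state[["R"]] <- min(1, max(0, state[["R"]]))
    keep <- out[, 1] %in% times
    keep[nrow(out)] <- keep[nrow(out)] & (b == duration || b %in% times)
    if (k > 1) keep[1] <- FALSE  # boundary row already reported by previous leg
    rows[[k]] <- out[keep, , drop = FALSE]
    inputs[[k]] <- cbind(ERKp = rep(ek, sum(keep)), JAKp = rep(jk, sum(keep)))
  }
  mat <- do.call(rbind, rows)
  inp <- do.call(rbind, inputs)

  if (min(mat[, -1]) < -1e-4) {
    stop("integration produced substantially negative amounts", call. = FALSE)
  }
  states <- mat[, -1, drop = FALSE]
  states[states < 0] <- 0
  states[, 15] <- pmin(1, states[, 15])
  colnames(states) <- state_names()

  traj <- data.frame(time_min = mat[, 1], states, inp, check.names = FALSE)
  traj$MITF_activity <- mitf_activity(states)
  traj$STAT3_activity <- stat3_activity(states)
  structure(traj,
            class = c("pias3net_trajectory", "data.frame"),
            params = params,
            solver = list(atol = atol, rtol = rtol, engine = engine,
                          method = "lsoda"),
            final_state = state)
}

#' Final state of a trajectory
#' @param traj A `"pias3net_trajectory"`.
#' @return Named state vector at the last reported time.
#' @export
final_state <- function(traj) {
  attr(traj, "final_state")
}

#' Linear interpolation of a trajectory column at given times
#' @param traj Trajectory.
#' @param column Column name.
#' @param at Times (minutes) within the trajectory span.
#' @return Numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, column, at) {
  stats::approx(traj$time_min, traj[[column]], xout = at, rule = 1)$y
}

#' Write a trajectory as tidy CSV
#' @param traj Trajectory.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Locate a steady state under constant inputs
#'
#' Integrates from `initial` (by default the empty state) for `horizon`
#' minutes and verifies that the right-hand side has relaxed: the largest
#' derivative, relative to the state scale, must fall below `tol`.  If
#' not, integration is extended up to four more horizons before failing.
#'
#' @param params Parameter vector.
#' @param erkp,jakp Constant inputs (au); default to the baselines.
#' @param initial Starting state for the relaxation.
#' @param horizon Integration horizon per attempt (minutes).
#' @param tol Convergence tolerance on `max |dx/dt| / max(|x|, eps)`
#'   per minute.
#' @param atol,rtol Integration tolerances.
#' @param engine Integration engine, as in [simulate_model()].
#' @return Named steady state vector, with the achieved residual in
#'   attribute `"residual"` and the total relaxation time in `"time"`.
#' @export
steady_state <- function(params = default_parameters(),
                         erkp = params[["ERKp_baseline"]],
                         jakp = params[["JAKp_baseline"]],
                         initial = NULL, horizon = 50000, tol = 1e-6,
                         atol = 1e-8, rtol = 1e-6,
                         engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  validate_parameters(params)
  state <- if (is.null(initial)) empty_state(params) else initial
  total_t <- 0
  for (attempt in 1:5) {
    out <- integrate_segment(state, c(0, horizon), params, erkp, jakp,
                             atol, rtol, engine)
    state <- stats::setNames(as.numeric(out[nrow(out), -1]), state_names())
    state[state < 0] <- 0
    state[["R"]] <- min(1, max(0, state[["R"]]))
    total_t <- total_t + horizon
    d <- model_rhs(0, state, params, erkp, jakp)
    scale <- max(abs(state), 1)
    res <- max(abs(d) / pmax(abs(state), 1e-3 * scale))
    if (res < tol) {
      return(structure(state, residual = res, time = total_t))
    }
  }
  stop(sprintf(
    "no steady state within %g min (residual %.3g, tol %.3g) at ERKp=%g, JAKp=%g",
    total_t, res, tol, erkp, jakp), call. = FALSE)
}
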
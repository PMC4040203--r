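#' Muscle-fiber oculomotor plant parameters (element level)
#'
#' The plant is 2n columns of m series muscle fibers: each column carries
#' two tendon elements (series elasticity `K_se`, viscosity `B_2`) at its
#' ends and m fiber elements (passive elasticity `K_lt`, viscosity `B_1`,
#' active-state generator F) in between, all acting on the eyeball
#' (inertia `J_p`, viscosity `B_p`, passive elasticity `K_p`, radius `r`).
#' All mechanical parameters are element-level SI values (N/m, N s/m,
#' N s^2/m, m); see [fiber_parameter_scaling()] to derive them from
#' whole-muscle values.  Stretches are deviations about the pre-stretched
#' primary position (the anatomical pre-stretch, 3.705 mm, does not enter
#' the linear dynamics).
#'
#' @param K_se tendon elasticity (N/m).
#' @param B_2 tendon viscosity (N s/m).
#' @param K_lt fiber passive elasticity (N/m).
#' @param B_1 fiber viscosity (N s/m).
#' @param J_p eyeball inertia term (N s^2/m).
#' @param B_p eyeball viscosity (N s/m).
#' @param K_p eyeball passive elasticity (N/m).
#' @param r eyeball radius (m).
#' @param n columns per muscle.
#' @param m fibers per column.
#' @param stretch primary-position muscle pre-stretch (m), kept for
#'   reporting.
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(K_se = 250, B_2 = 1, K_lt = 6070, B_1 = 560,
                         J_p = 2.2e-3, B_p = 0.618, K_p = 16.34,
                         r = 0.01, n = 1L, m = 100L, stretch = 3.705e-3) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(K_se > 0, B_2 > 0, K_lt > 0, B_1 > 0, J_p > 0, B_p > 0,
            K_p > 0, r > 0, n >= 1L, m >= 1L)
  structure(list(K_se = K_se, B_2 = B_2, K_lt = K_lt, B_1 = B_1,
                 J_p = J_p, B_p = B_p, K_p = K_p, r = r, n = n, m = m,
                 stretch = stretch),
            class = "plant_params")
}

#' Scale whole-muscle parameters to the fiber level
#'
#' A column of two tendon elements and m fiber elements in series must
#' aggregate back to the whole-muscle values: series elasticities scale up
#' by the series count (each of the two tendon elements is `2 K_se`, each
#' fiber `m K_lt`; likewise the viscosities), and with n parallel columns
#' each fiber's active-state tension is the whole-muscle tension divided
#' by n (reported as `force_scale`).
#'
#' @param whole list with whole-muscle `K_se`, `B_2`, `K_lt`, `B_1`,
#'   `J_p`, `B_p`, `K_p`, `r` (SI units).
#' @param n columns per muscle.
#' @param m fibers per column.
#' @return A [plant_params()]; the per-fiber force scale is in attribute
#'   `force_scale`.
#' @export
fiber_parameter_scaling <- function(whole, n = 1L, m = 100L) {
  p <- plant_params(K_se = 2 * whole$K_se, B_2 = 2 * whole$B_2,
                    K_lt = m * whole$K_lt, B_1 = m * whole$B_1,
                    J_p = whole$J_p, B_p = whole$B_p, K_p = whole$K_p,
                    r = whole$r, n = n, m = m,
                    stretch = if (is.null(whole$stretch)) 3.705e-3
                              else whole$stretch)
  attr(p, "force_scale") <- 1 / n
  p
}

#' Column tension from the series constraint
#'
#' Every element stretch-rate is affine in the column tension `T_i`, so
#' the requirement that the stretch-rates sum to the muscle end velocity
#' yields one linear equation in `T_i`.  Agonist and antagonist columns
#' differ by the printed sign convention.
#'
#' @param y element stretches, length m + 2 (tendon, m fibers, tendon; m).
#' @param xdot muscle end velocity (m/s).
#' @param F active-state tensions of the m fiber elements (N).
#' @param params a [plant_params()].
#' @param side `"agonist"` or `"antagonist"`.
#' @return Column tension `T_i` (N).
#' @export
column_tension <- function(y, xdot, F, params, side = c("agonist",
                                                        "antagonist")) {
  side <- match.arg(side)
  m <- params$m
  stopifnot(length(y) == m + 2, length(F) == m)
  den <- 2 / params$B_2 + m / params$B_1
  if (den <= 0) stop("degenerate series coefficient")
  if (side == "agonist") {
    s <- (params$K_se / params$B_2) * (y[1] + y[m + 2]) +
      sum(params$K_lt * y[2:(m + 1)] - F) / params$B_1
    -(xdot + s) / den
  } else {
    s <- (params$K_se / params$B_2) * (y[1] + y[m + 2]) +
      sum(params$K_lt * y[2:(m + 1)] + F) / params$B_1
    (xdot + s) / den
  }
}

#' Net muscle torques
#'
#' Net agonist and antagonist muscle forces acting on the eyeball,
#' `T_ag = -n (K_se y_1 + B_2 ydot_1)` and
#' `T_ant = +n (K_se y_1 + B_2 ydot_1)` summed over identical columns.
#' With the tendon state equations these sums reduce exactly to n times
#' the column tension.
#'
#' @param state list with `x`, `xd` (m, m/s) and stretch vectors `y_ag`,
#'   `y_ant` (length m + 2).
#' @param forcing list with per-fiber tensions `F_ag`, `F_ant` (length m).
#' @param params a [plant_params()].
#' @return List with `T_ag`, `T_ant` (N).
#' @export
muscle_torques <- function(state, forcing, params) {
  Ta <- column_tension(state$y_ag, state$xd, forcing$F_ag, params,
                       "agonist")
  ya1d <- -(Ta + params$K_se * state$y_ag[1]) / params$B_2
  Tag <- -params$n * (params$K_se * state$y_ag[1] + params$B_2 * ya1d)
  Tt <- column_tension(state$y_ant, state$xd, forcing$F_ant, params,
                       "antagonist")
  yt1d <- (Tt - params$K_se * state$y_ant[1]) / params$B_2
  Tant <- params$n * (params$K_se * state$y_ant[1] + params$B_2 * yt1d)
  list(T_ag = Tag, T_ant = Tant)
}

#' Plant state derivatives
#'
#' Reference (R-level) implementation of the full plant vector field:
#' column tensions are resolved algebraically, stretch rates follow the
#' element state equations, and the eyeball obeys
#' `T_ag - T_ant = J_p r thetadd + B_p r thetad + K_p r theta` written in
#' the arc-length coordinate `x = r theta`.
#'
#' @inheritParams muscle_torques
#' @return List with `dx`, `dxd`, `dy_ag`, `dy_ant`, `T_ag`, `T_ant`.
#' @export
plant_derivatives <- function(state, forcing, params) {
  m <- params$m
  Ta <- column_tension(state$y_ag, state$xd, forcing$F_ag, params,
                       "agonist")
  Tt <- column_tension(state$y_ant, state$xd, forcing$F_ant, params,
                       "antagonist")
  dy_ag <- numeric(m + 2)
  dy_ag[c(1, m + 2)] <- -(Ta + params$K_se * state$y_ag[c(1, m + 2)]) /
    params$B_2
  dy_ag[2:(m + 1)] <- (-Ta - params$K_lt * state$y_ag[2:(m + 1)] +
                         forcing$F_ag) / params$B_1
  dy_ant <- numeric(m + 2)
  dy_ant[c(1, m + 2)] <- (Tt - params$K_se * state$y_ant[c(1, m + 2)]) /
    params$B_2
  dy_ant[2:(m + 1)] <- (Tt - params$K_lt * state$y_ant[2:(m + 1)] -
                          forcing$F_ant) / params$B_1
  Tag <- params$n * Ta
  Tant <- params$n * Tt
  dxd <- (Tag - Tant - params$B_p * state$xd - params$K_p * state$x) /
    params$J_p
  list(dx = state$xd, dxd = dxd, dy_ag = dy_ag, dy_ant = dy_ant,
       T_ag = Tag, T_ant = Tant)
}

#' Static equilibrium of the plant
#'
#' Solves the linear static system (all rates zero) for the column
#' tensions and the eye position given uniform or per-fiber active-state
#' tensions.
#'
#' @param params a [plant_params()].
#' @param F_ag,F_ant per-fiber active-state tensions (N); scalars are
#'   recycled to the m fibers.
#' @return List with `x` (m), `theta_deg`, `T_a`, `T_t` (column tensions)
#'   and stretch vectors `y_ag`, `y_ant`.
#' @export
plant_equilibrium <- function(params, F_ag, F_ant) {
  m <- params$m
  Fa <- rep_len(F_ag, m); Ft <- rep_len(F_ant, m)
  A <- rbind(c(-2 / params$K_se - m / params$K_lt, 0, -1),
             c(0, 2 / params$K_se + m / params$K_lt, -1),
             c(params$n, -params$n, -params$K_p))
  b <- c(-sum(Fa) / params$K_lt, sum(Ft) / params$K_lt, 0)
  sol <- solve(A, b)
  Ta <- sol[1]; Tt <- sol[2]; x <- sol[3]
  list(x = x, theta_deg = x / params$r * 180 / pi, T_a = Ta, T_t = Tt,
       y_ag = c(-Ta / params$K_se, (Fa - Ta) / params$K_lt,
                -Ta / params$K_se),
       y_ant = c(Tt / params$K_se, (Tt - Ft) / params$K_lt,
                 Tt / params$K_se))
}

#' Position gained per newton of differential fixation tension
#'
#' Linear gain `d theta / d dF` of the static plant when the differential
#' tension `dF` is split `alpha` to the agonist and `1 - alpha` off the
#' antagonist.  Used to invert the equilibrium map when calibrating
#' fixation tensions.
#'
#' @param params a [plant_params()].
#' @param F_0 common fixation tension (N); cancels by linearity.
#' @param alpha agonist share of the differential tension.
#' @return Gain in degrees per newton.
#' @export
equilibrium_gain <- function(params, F_0 = 0.4, alpha = 0.55) {
  e1 <- plant_equilibrium(params, F_0 + alpha, F_0 - (1 - alpha))
  e0 <- plant_equilibrium(params, F_0, F_0)
  e1$theta_deg - e0$theta_deg
}

#' Simulate the muscle-fiber plant
#'
#' Fixed-step RK4 integration of the full plant driven by per-fiber
#' active-state tension traces.  Fibers sharing a tension trace are passed
#' as groups to keep the forcing compact; the initial condition is the
#' static equilibrium under the first forcing sample.
#'
#' @param time uniform sample times (ms) of the forcing traces.
#' @param F_ag_groups matrix (length(time) x n_groups) of agonist tension
#'   traces (N), or a vector for a single group.
#' @param fiber_group integer vector (length m) assigning each agonist
#'   fiber to a column of `F_ag_groups`.
#' @param F_ant antagonist tension trace (vector, N; shared by all
#'   antagonist fibers).
#' @param params a [plant_params()].
#' @return List with `time` (ms), `theta` (deg), `theta_dot` (deg/s),
#'   `T_ag`, `T_ant` (N) and the saccade metrics of [saccade_metrics()].
#' @export
simulate_plant <- function(time, F_ag_groups, fiber_group = NULL, F_ant,
                           params) {
  if (is.null(dim(F_ag_groups)))
    F_ag_groups <- matrix(F_ag_groups, ncol = 1)
  if (is.null(fiber_group)) fiber_group <- rep(1L, params$m)
  stopifnot(nrow(F_ag_groups) == length(time),
            length(F_ant) == length(time),
            length(fiber_group) == params$m)
  dt_s <- (time[2] - time[1]) / 1000
  Fa0 <- F_ag_groups[1, fiber_group]
  eq <- plant_equilibrium(params, Fa0, F_ant[1])
  out <- cpp_simulate_plant(F_ag_groups, as.integer(fiber_group) - 1L,
                            as.numeric(F_ant), params,
                            eq$y_ag, eq$y_ant, eq$x, 0, dt_s)
  res <- list(time = time, theta = out$theta, theta_dot = out$theta_dot,
              T_ag = out$T_ag, T_ant = out$T_ant)
  res$metrics <- saccade_metrics(time, out$theta, out$theta_dot)
  res
}

#' Saccade metrics from an eye-position trace
#'
#' Onset and end are the first and last times the absolute eye velocity
#' exceeds the detection threshold (default 10 deg/s) within the movement
#' episode containing the velocity peak; magnitude is the position change
#' across that episode.
#'
#' @param time sample times (ms).
#' @param theta eye position (deg).
#' @param theta_dot eye velocity (deg/s); differenced from `theta` when
#'   missing.
#' @param threshold velocity criterion (deg/s).
#' @return List with `onset_ms`, `end_ms`, `duration_ms`,
#'   `peak_velocity_deg_s`, `magnitude_deg`, `final_deg`.
#' @export
saccade_metrics <- function(time, theta, theta_dot = NULL,
                            threshold = 10) {
  if (is.null(theta_dot))
    theta_dot <- c(diff(theta) / diff(time) * 1000, 0)
  v <- abs(theta_dot)
  ipk <- which.max(v)
  if (v[ipk] < threshold)
    return(list(onset_ms = NA_real_, end_ms = NA_real_,
                duration_ms = 0, peak_velocity_deg_s = max(v),
                magnitude_deg = 0, final_deg = theta[length(theta)]))
  below <- v < threshold
  i0 <- ipk; while (i0 > 1 && !below[i0 - 1]) i0 <- i0 - 1
  i1 <- ipk; while (i1 < length(v) && !below[i1 + 1]) i1 <- i1 + 1
  list(onset_ms = time[i0], end_ms = time[i1],
       duration_ms = time[i1] - time[i0],
       peak_velocity_deg_s = theta_dot[ipk],
       magnitude_deg = theta[i1] - theta[i0],
       final_deg = theta[length(theta)])
}
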
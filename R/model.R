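## Core mitotic-entry network.
##
## State vector (all concentrations in a.u.):
##   cdc25    unphosphorylated cdc25
##   cdc25pp  bi-phosphorylated, active cdc25
##   cycbcdk1 active (Tyr15-dephosphorylated) cdk1-cyclin B
##   wee1     active wee1/myt1
##   pp2ab55  active PP2A-B55
##   subp     phosphorylated cdk1 substrate
## Mono-phosphorylated cdc25 is implicit through the conservation relation
## cdc25p = cdc25_tot - cdc25 - cdc25pp. PLK1 is an algebraic input.

state_names <- c("cdc25", "cdc25pp", "cycbcdk1", "wee1", "pp2ab55", "subp")

#' Construct and validate a network state
#'
#' @param cdc25,cdc25pp,cycbcdk1,wee1,pp2ab55,subp state concentrations
#'   (a.u.); see the package vignette for the network wiring.
#' @param params a [kinetic_params()] object used to check pool bounds.
#' @return Named numeric vector of class `network_state`.
#' @export
network_state <- function(cdc25, cdc25pp, cycbcdk1, wee1, pp2ab55, subp,
                          params = NULL) {
  s <- c(cdc25 = cdc25, cdc25pp = cdc25pp, cycbcdk1 = cycbcdk1,
         wee1 = wee1, pp2ab55 = pp2ab55, subp = subp)
  if (!is.null(params)) check_state(s, params)
  class(s) <- c("network_state", class(s))
  s
}

check_state <- function(state, params, tol = 1e-9) {
  s <- as_state_vector(state)
  if (any(s < -tol)) stop("negative state component")
  if (s[["cdc25"]] + s[["cdc25pp"]] > params$cdc25_tot + tol)
    stop("cdc25 conservation violated: cdc25 + cdc25pp exceeds cdc25_tot")
  if (s[["subp"]] > params$sub_tot + tol)
    stop("subp exceeds sub_tot")
  if (s[["cycbcdk1"]] > params$cycbcdk1_tot + tol)
    stop("cycbcdk1 exceeds cycbcdk1_tot")
  invisible(TRUE)
}

as_state_vector <- function(state) {
  s <- unlist(state)[state_names]
  if (anyNA(s)) stop("state must contain components: ",
                     paste(state_names, collapse = ", "))
  s
}

#' PLK1 activity from the inhibition fraction
#'
#' PLK1 is activated downstream of cdk2-cyclin A; its activity is modelled
#' as `f_plk1 * cyca_cdk2_tot`, with `f_plk1` sweeping from 1 (fully
#' active) to 0 (complete inhibition, e.g. saturating BI 2536).
#'
#' @param f_plk1 inhibition fraction in `[0, 1]`.
#' @param cyca_cdk2_tot cdk2-cyclin A activity (a.u.).
#' @return PLK1 activity (a.u.).
#' @export
plk1_activity <- function(f_plk1, cyca_cdk2_tot) {
  if (!is.numeric(f_plk1) || any(f_plk1 < 0) || any(f_plk1 > 1))
    stop("f_plk1 must lie in [0, 1]")
  if (any(cyca_cdk2_tot < 0)) stop("cyca_cdk2_tot must be >= 0")
  f_plk1 * cyca_cdk2_tot
}

#' Time derivatives of the cdc25 phosphorylation cycle
#'
#' cdc25 is phosphorylated twice by cdk1-cyclin B and PLK1 and
#' dephosphorylated by PP2A-B55 and a constitutive phosphatase; the
#' mono-phosphorylated form follows from conservation:
#' \deqn{d[Cdc25]/dt = (k_{PPX} + k_{B55,Cdc25}[PP2AB55])[Cdc25p]
#'   - (k_{Cdk1,Cdc25} V_{Cdk1} + k_{Plk1,Cdc25}[Plk1])[Cdc25]}
#' \deqn{d[Cdc25pp]/dt = -(k_{PPX} + k_{B55,Cdc25}[PP2AB55])[Cdc25pp]
#'   + (k_{Cdk1,Cdc25} V_{Cdk1} + k_{Plk1,Cdc25}[Plk1])[Cdc25p]}
#' with \eqn{[Cdc25p] = [Cdc25_{Tot}] - [Cdc25] - [Cdc25pp]},
#' \eqn{V_{Cdk1} = [CycBCdk1]} and \eqn{[Plk1] = f_{Plk1}[CycACdk2_{Tot}]}.
#'
#' @param state a state vector (see [network_state()]).
#' @param params a [kinetic_params()] object.
#' @return Numeric vector `c(d_cdc25, d_cdc25pp)` (a.u./h).
#' @export
cdc25_rhs <- function(state, params) {
  s <- as_state_vector(state)
  cdc25p <- params$cdc25_tot - s[["cdc25"]] - s[["cdc25pp"]]
  if (cdc25p < -1e-9)
    stop("cdc25 conservation violated: negative mono-phosphorylated pool")
  v_cdk1 <- s[["cycbcdk1"]]
  plk1 <- plk1_activity(params$f_plk1, params$cyca_cdk2_tot)
  phos <- params$k_cdk1_cdc25 * v_cdk1 + params$k_plk1_cdc25 * plk1
  dephos <- params$k_ppx_y15 + params$k_b55_cdc25 * s[["pp2ab55"]]
  c(d_cdc25 = dephos * cdc25p - phos * s[["cdc25"]],
    d_cdc25pp = -dephos * s[["cdc25pp"]] + phos * cdc25p)
}

#' Time derivative of cdk1 substrate phosphorylation
#'
#' \deqn{d[Subp]/dt = k_{Cdk1,Sub} V_{Cdk1} ([Sub_{Tot}] - [Subp])
#'   - k_{B55,Sub} [PP2AB55] [Subp]}
#' The fraction `subp / sub_tot` is the model's read-out of cdk substrate
#' phosphorylation (the FRET-probe proxy); NEBD is declared when it reaches
#' `nebd_threshold`.
#'
#' @inheritParams cdc25_rhs
#' @return Scalar derivative (a.u./h).
#' @export
substrate_rhs <- function(state, params) {
  s <- as_state_vector(state)
  if (s[["subp"]] < -1e-9 || s[["subp"]] > params$sub_tot + 1e-9)
    stop("subp outside [0, sub_tot]")
  params$k_cdk1_sub * s[["cycbcdk1"]] * (params$sub_tot - s[["subp"]]) -
    params$k_b55_sub * s[["pp2ab55"]] * s[["subp"]]
}

#' Full network right-hand side
#'
#' Concatenates the cdc25 cycle, the substrate equation, and the auxiliary
#' submodel: cdk1-cyclin B activated through Tyr15 dephosphorylation by
#' active cdc25 (plus a small basal term) and inactivated by wee1/myt1;
#' wee1 switched off by cdk1 (feedback) and by cdk2-cyclin A (the
#' PLK1-independent entry route) and reactivated with PP2A-B55 help;
#' PP2A-B55 inactivated downstream of cdk1 (greatwall/ENSA limb collapsed
#' to one step). In `reduced` mode `cycbcdk1` (as the kinase activity
#' `v_cdk1`) and `pp2ab55` are clamped at supplied constants and their own
#' derivatives (with wee1's) are zero, so the cdc25 and substrate equations
#' can be exercised in isolation against closed-form oracles.
#'
#' @inheritParams cdc25_rhs
#' @param reduced clamp `v_cdk1` and `pp2ab55`?
#' @param clamp named list with elements `v_cdk1` and `pp2ab55` used when
#'   `reduced = TRUE`.
#' @return Named derivative vector over the six states (a.u./h).
#' @export
network_rhs <- function(state, params, reduced = FALSE,
                        clamp = list(v_cdk1 = 0, pp2ab55 = 0)) {
  s <- as_state_vector(state)
  if (reduced) {
    if (!all(c("v_cdk1", "pp2ab55") %in% names(clamp)))
      stop("reduced mode requires clamp$v_cdk1 and clamp$pp2ab55")
    s[["cycbcdk1"]] <- clamp$v_cdk1
    s[["pp2ab55"]] <- clamp$pp2ab55
  }
  d25 <- cdc25_rhs(s, params)
  dsub <- substrate_rhs(s, params)
  if (reduced) {
    out <- c(d25[[1]], d25[[2]], 0, 0, 0, dsub)
  } else {
    ap <- params$auxiliary_params
    v <- s[["cycbcdk1"]]
    act_cdk1 <- (ap$k_cdc25_basal + ap$k_cdc25_act * s[["cdc25pp"]]) *
      (params$cycbcdk1_tot - v)
    inact_cdk1 <- (ap$k_wee1_basal + ap$k_wee1_inact * s[["wee1"]]) * v
    d_wee1 <- (ap$k_wee1_act + ap$k_b55_wee1 * s[["pp2ab55"]]) *
      (ap$wee1_tot - s[["wee1"]]) -
      (ap$k_cdk1_wee1 * v + ap$k_cdk2_wee1 * params$cyca_cdk2_tot) *
      s[["wee1"]]
    d_b55 <- ap$k_b55_act * (ap$b55_tot - s[["pp2ab55"]]) -
      ap$k_cdk1_b55 * v * s[["pp2ab55"]]
    out <- c(d25[[1]], d25[[2]], act_cdk1 - inact_cdk1, d_wee1, d_b55, dsub)
  }
  names(out) <- state_names
  out
}

#' Interphase initial condition
#'
#' The pre-G2 resting state: cdc25 fully unphosphorylated, no substrate
#' phosphorylation, and the cdk1/wee1/PP2A-B55 limb relaxed to its stable
#' interphase fixed point at zero cdk2-cyclin A input (computed by damped
#' fixed-point iteration, not hard-coded).
#'
#' @param params a [kinetic_params()] object.
#' @return A `network_state` vector.
#' @export
interphase_state <- function(params) {
  p0 <- params
  p0$cyca_cdk2_tot <- 0
  ap <- params$auxiliary_params
  ## with cdc25pp = 0 the interphase fixed point solves a small algebraic
  ## system; iterate v -> (wee1, b55) -> v until converged
  v <- 0; wee1 <- ap$wee1_tot; b55 <- ap$b55_tot
  for (i in 1:500) {
    wee1_new <- (ap$k_wee1_act + ap$k_b55_wee1 * b55) * ap$wee1_tot /
      ((ap$k_wee1_act + ap$k_b55_wee1 * b55) + ap$k_cdk1_wee1 * v)
    b55_new <- ap$k_b55_act * ap$b55_tot /
      (ap$k_b55_act + ap$k_cdk1_b55 * v)
    v_new <- ap$k_cdc25_basal * params$cycbcdk1_tot /
      (ap$k_cdc25_basal + ap$k_wee1_basal + ap$k_wee1_inact * wee1_new)
    delta <- max(abs(c(wee1_new - wee1, b55_new - b55, v_new - v)))
    wee1 <- wee1_new; b55 <- b55_new; v <- v_new
    if (delta < 1e-13) break
  }
  network_state(cdc25 = params$cdc25_tot, cdc25pp = 0, cycbcdk1 = v,
                wee1 = wee1, pp2ab55 = b55, subp = 0, params = params)
}

#' Simulate a single cell from G2 entry to NEBD
#'
#' G2 entry is modelled as a step of cdk2-cyclin A activity from 0 to
#' `params$cyca_cdk2_tot` at `t = 0`, starting from the interphase state.
#' The network is integrated with a stiff-capable solver
#' (\code{deSolve::\link[deSolve]{lsoda}}, rtol 1e-8 / atol 1e-10) on a
#' dense output grid; NEBD is the first time the substrate-phosphorylation
#' fraction reaches `params$nebd_threshold` (linearly interpolated between
#' output samples), censored at `horizon` otherwise.
#'
#' @param params a [kinetic_params()] object.
#' @param horizon simulation horizon (h), default 24.
#' @param output_step output grid step (h), default 0.01.
#' @param stop_at_nebd terminate the integration at the NEBD event (the
#'   event time then comes from the solver's root finder)? Default FALSE:
#'   the full course to `horizon` is returned and the event time is
#'   interpolated with [detect_nebd()].
#' @param reduced,clamp forwarded to [network_rhs()].
#' @param init optional initial state overriding [interphase_state()].
#' @return A `cell_trajectory`: list with `times`, `states` (matrix with one
#'   column per state plus `sub_frac`), `nebd_time` (NA if censored),
#'   `censored`, `censor_time`, `params`.
#' @export
simulate_cell <- function(params, horizon = 24, output_step = 0.01,
                          stop_at_nebd = FALSE, reduced = FALSE,
                          clamp = list(v_cdk1 = 0, pp2ab55 = 0),
                          init = NULL) {
  stopifnot(horizon > 0, output_step > 0)
  y0 <- if (is.null(init)) interphase_state(params) else as_state_vector(init)
  times <- seq(0, horizon, by = output_step)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  deriv <- function(t, y, parms) {
    list(network_rhs(y, params, reduced = reduced, clamp = clamp))
  }
  if (stop_at_nebd) {
    thr <- params$nebd_threshold * params$sub_tot
    sol <- deSolve::lsodar(y = as_state_vector(y0), times = times,
                           func = deriv, parms = NULL,
                           rtol = 1e-8, atol = 1e-10,
                           rootfunc = function(t, y, parms) y[["subp"]] - thr)
  } else {
    sol <- deSolve::lsoda(y = as_state_vector(y0), times = times,
                          func = deriv, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(sol, "istate")[1], ")")
  troot <- attr(sol, "troot")
  states <- sol[, state_names, drop = FALSE]
  traj <- list(
    times = sol[, "time"],
    states = cbind(states, sub_frac = states[, "subp"] / params$sub_tot),
    censor_time = horizon,
    params = params
  )
  if (stop_at_nebd && !is.null(troot) && length(troot) > 0) {
    traj$nebd_time <- troot[1]
    traj$censored <- FALSE
  } else {
    nt <- detect_nebd(traj, params$nebd_threshold)
    traj$nebd_time <- nt
    traj$censored <- is.na(nt)
  }
  class(traj) <- "cell_trajectory"
  traj
}

#' First upward crossing of the substrate-phosphorylation threshold
#'
#' Scans the trajectory's substrate fraction for the first upward crossing
#' of `threshold` and linearly interpolates between the bracketing output
#' samples. Returns `NA` (censored) if the threshold is never reached.
#'
#' @param trajectory a `cell_trajectory`, or any list with `times` and a
#'   `states` matrix containing a `sub_frac` column.
#' @param threshold crossing level, default the trajectory's own
#'   `nebd_threshold` (0.30 for the shipped calibration).
#' @return Crossing time in hours, or `NA_real_`.
#' @export
detect_nebd <- function(trajectory, threshold = NULL) {
  if (is.null(threshold)) threshold <- trajectory$params$nebd_threshold
  tt <- trajectory$times
  if (length(tt) < 2) stop("trajectory needs at least 2 samples")
  if (any(diff(tt) <= 0)) stop("time grid must be strictly increasing")
  f <- trajectory$states[, "sub_frac"]
  if (f[1] >= threshold) return(tt[1])
  above <- which(f >= threshold)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  t0 <- tt[i - 1]; t1 <- tt[i]
  f0 <- f[i - 1]; f1 <- f[i]
  t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("<cell_trajectory>",
      sprintf("  %d samples over [0, %g] h", length(x$times), x$censor_time),
      if (isTRUE(x$censored)) "  NEBD: censored"
      else sprintf("  NEBD at %.3f h", x$nebd_time),
      sep = "\n")
  invisible(x)
}

#' Export a trajectory as a data frame / CSV
#'
#' @param trajectory a `cell_trajectory`.
#' @param path optional CSV path; when given the frame is also written.
#' @return Data frame with time, each state, and the substrate fraction.
#' @export
trajectory_frame <- function(trajectory, path = NULL) {
  df <- data.frame(time = trajectory$times, trajectory$states,
                   check.names = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
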
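## Steady-state and saddle-node analysis of the network as a function of
## cdk2-cyclin A activity.
##
## At a fixed point every state is an explicit function of the active
## cdk1-cyclin B level v: PP2A-B55 and wee1 balance their on/off fluxes,
## the cdc25 cycle settles to the ratio distribution set by its kinase and
## phosphatase activities, and subp follows v and PP2A-B55. The fixed-point
## condition therefore reduces exactly to one scalar equation g(v) = 0,
## which is scanned on a dense lattice over [0, cycbcdk1_tot] and each
## bracketed root refined by bisection -- a brute-force search that cannot
## miss branches, in place of pseudo-arclength continuation.

## quasi-steady values of the remaining states given v
qss_at_v <- function(v, params) {
  ap <- params$auxiliary_params
  b55 <- ap$k_b55_act * ap$b55_tot / (ap$k_b55_act + ap$k_cdk1_b55 * v)
  wee_on <- ap$k_wee1_act + ap$k_b55_wee1 * b55
  wee_off <- ap$k_cdk1_wee1 * v + ap$k_cdk2_wee1 * params$cyca_cdk2_tot
  wee1 <- wee_on * ap$wee1_tot / (wee_on + wee_off)
  plk1 <- plk1_activity(params$f_plk1, params$cyca_cdk2_tot)
  kin <- params$k_cdk1_cdc25 * v + params$k_plk1_cdc25 * plk1
  ph <- params$k_ppx_y15 + params$k_b55_cdc25 * b55
  r <- kin / ph
  z <- 1 + r + r^2
  cdc25 <- params$cdc25_tot / z
  cdc25pp <- params$cdc25_tot * r^2 / z
  ksub <- params$k_cdk1_sub * v
  subp <- if (ksub + params$k_b55_sub * b55 > 0)
    params$sub_tot * ksub / (ksub + params$k_b55_sub * b55) else 0
  network_state(cdc25 = cdc25, cdc25pp = cdc25pp, cycbcdk1 = v,
                wee1 = wee1, pp2ab55 = b55, subp = subp)
}

## scalar fixed-point residual in v
g_scalar <- function(v, params) {
  s <- qss_at_v(v, params)
  ap <- params$auxiliary_params
  (ap$k_cdc25_basal + ap$k_cdc25_act * s[["cdc25pp"]]) *
    (params$cycbcdk1_tot - v) -
    (ap$k_wee1_basal + ap$k_wee1_inact * s[["wee1"]]) * v
}

## finite-difference Jacobian of the full 6-state system
fd_jacobian <- function(state, params, h = 1e-7) {
  s <- as_state_vector(state)
  n <- length(s)
  f0 <- network_rhs(s, params)
  J <- matrix(0, n, n, dimnames = list(state_names, state_names))
  for (j in seq_len(n)) {
    hp <- h * max(1, abs(s[j]))
    sp <- s; sp[j] <- sp[j] + hp
    sm <- s; sm[j] <- sm[j] - hp
    ## state components may not go negative for the rhs guards
    dn <- if (sm[j] < 0) { sm[j] <- 0; sp[j] - sm[j] } else 2 * hp
    J[, j] <- (network_rhs(sp, params) - network_rhs(sm, params)) / dn
  }
  f0 <- f0 # silence lints; Jacobian only
  J
}

classify_stability <- function(state, params, margin = 1e-9) {
  ev <- eigen(fd_jacobian(state, params), only.values = TRUE)$values
  lead <- max(Re(ev))
  if (abs(lead) < margin) "indeterminate" else
    if (lead < 0) "stable" else "unstable"
}

## all fixed points at the parameter value baked into params
fixed_points_at <- function(params, n_scan = 2000, tol = 1e-12) {
  vmax <- params$cycbcdk1_tot
  v <- seq(0, vmax, length.out = n_scan + 1)
  gv <- vapply(v, g_scalar, 0, params = params)
  roots <- numeric(0)
  for (i in which(diff(sign(gv)) != 0)) {
    r <- stats::uniroot(g_scalar, c(v[i], v[i + 1]), params = params,
                        tol = tol)$root
    roots <- c(roots, r)
  }
  exact <- which(gv == 0)
  roots <- sort(unique(c(roots, v[exact])))
  ## dedup within relative tolerance on the state norm
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-6 * max(1, vmax))
    roots <- roots[keep]
  }
  lapply(roots, function(r) {
    s <- qss_at_v(r, params)
    list(state = s, residual = max(abs(network_rhs(s, params))),
         stability = classify_stability(s, params))
  })
}

#' Steady-state branches over a cdk2-cyclin A grid
#'
#' For each grid value of cdk2-cyclin A activity, finds all fixed points of
#' the full network by a dense bracketing scan of the (exact) scalar
#' fixed-point equation, verifies each against [network_rhs()], and
#' classifies stability by the eigenvalues of a finite-difference Jacobian.
#' Grid values where the scan fails are recorded with `stability = "gap"`
#' rather than raising.
#'
#' @param params a [kinetic_params()] object; its own `cyca_cdk2_tot` is
#'   ignored in favour of the grid.
#' @param parameter_grid increasing vector of cdk2-cyclin A activities.
#' @param n_scan lattice density of the bracketing scan.
#' @return Data frame with `cyca_cdk2_tot`, the six state components,
#'   `residual` (norm of the rhs) and `stability`
#'   (stable / unstable / indeterminate).
#' @export
steady_states <- function(params, parameter_grid, n_scan = 2000) {
  if (length(parameter_grid) == 0 || is.unsorted(parameter_grid))
    stop("parameter_grid must be non-empty and increasing")
  rows <- list()
  for (a in parameter_grid) {
    p <- params
    p$cyca_cdk2_tot <- a
    fps <- tryCatch(fixed_points_at(p, n_scan = n_scan),
                    error = function(e) NULL)
    if (is.null(fps)) {
      rows[[length(rows) + 1]] <- data.frame(
        cyca_cdk2_tot = a, t(stats::setNames(rep(NA_real_, 6), state_names)),
        residual = NA_real_, stability = "gap")
      next
    }
    for (fp in fps) {
      rows[[length(rows) + 1]] <- data.frame(
        cyca_cdk2_tot = a, t(fp$state[state_names]),
        residual = fp$residual, stability = fp$stability)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

count_stable_at <- function(params, a, n_scan = 2000) {
  p <- params
  p$cyca_cdk2_tot <- a
  fps <- fixed_points_at(p, n_scan = n_scan)
  sum(vapply(fps, function(f) f$stability == "stable", TRUE))
}

#' Saddle-node points of the bistable window
#'
#' Locates the cdk2-cyclin A activities at which the number of stable
#' steady states changes, by coarse scanning of `bounds` followed by
#' bisection to a resolution of `1e-3` of the bounds width. `sn_upper` is
#' the activity threshold above which only the high cdk1-cyclin B state
#' exists; PLK1 inhibition moves it up.
#'
#' @param params a [kinetic_params()] object (carries `f_plk1`).
#' @param bounds length-2 interval of cdk2-cyclin A activity to search.
#' @param n_coarse number of coarse scan points.
#' @return List with `f_plk1`, `bistable` (logical), and when bistable the
#'   `sn_lower` / `sn_upper` bracketing activities (clipped to `bounds` if
#'   the window extends past them).
#' @export
find_saddle_nodes <- function(params, bounds = c(1e-3, 10), n_coarse = 80) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  grid <- seq(bounds[1], bounds[2], length.out = n_coarse)
  ns <- vapply(grid, function(a) count_stable_at(params, a), 0L)
  bist <- ns >= 2
  if (!any(bist))
    return(list(f_plk1 = params$f_plk1, bistable = FALSE,
                sn_lower = NA_real_, sn_upper = NA_real_))
  res <- 1e-3 * diff(bounds)
  bisect_edge <- function(lo, hi, lo_bist) {
    ## invariant: bistability holds at the end flagged by lo_bist
    while (hi - lo > res) {
      mid <- (lo + hi) / 2
      m_bist <- count_stable_at(params, mid) >= 2
      if (m_bist == lo_bist) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  i1 <- which(bist)[1]
  i2 <- which(bist)[sum(bist)]
  sn_lower <- if (i1 == 1) bounds[1] else
    bisect_edge(grid[i1 - 1], grid[i1], lo_bist = FALSE)
  sn_upper <- if (i2 == n_coarse) bounds[2] else
    bisect_edge(grid[i2], grid[i2 + 1], lo_bist = TRUE)
  list(f_plk1 = params$f_plk1, bistable = TRUE,
       sn_lower = sn_lower, sn_upper = sn_upper)
}
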
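## NEBD timing in heterogeneous populations under graded PLK1 inhibition.
##
## Cell-to-cell variability enters through the cdk2-cyclin A activity only:
## each simulated cell draws one activity value and keeps it across all
## inhibition doses, mirroring a dose-response experiment on one population.

#' Define a population scenario
#'
#' @param mean,sd mean and standard deviation of the per-cell cdk2-cyclin A
#'   activity (a.u.).
#' @param n_cells number of cells (default 400).
#' @param distribution sampling family: `"truncnorm"` (normal redrawn at
#'   zero, the default), `"lognormal"` (matching mean/sd on the natural
#'   scale) or `"uniform"` (mean +/- sd*sqrt(3)).
#' @param name scenario identifier carried into result tables.
#' @return A `population_scenario` list.
#' @export
population_scenario <- function(mean, sd, n_cells = 400,
                                distribution = c("truncnorm", "lognormal",
                                                 "uniform"),
                                name = "scenario") {
  distribution <- match.arg(distribution)
  if (!is.finite(mean) || mean <= 0) stop("mean must be positive")
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(list(name = name, distribution = distribution, mean = mean,
                 sd = sd, n_cells = as.integer(n_cells)),
            class = "population_scenario")
}

#' Sample per-cell cdk2-cyclin A activities
#'
#' Draws `n_cells` activities from the scenario's distribution; for the
#' truncated-normal family, negative draws are redrawn until positive.
#' Reproducible under `seed`.
#'
#' @param scenario a [population_scenario()].
#' @param seed integer RNG seed.
#' @return Numeric vector of activities (a.u.), length `n_cells`.
#' @export
sample_population <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "population_scenario"))
  n <- scenario$n_cells
  m <- scenario$mean
  s <- scenario$sd
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(function() {
    switch(scenario$distribution,
      truncnorm = {
        x <- stats::rnorm(n, m, s)
        while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), m, s)
        x
      },
      lognormal = {
        if (s == 0) rep(m, n) else {
          sdlog <- sqrt(log(1 + (s / m)^2))
          stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
        }
      },
      uniform = {
        h <- s * sqrt(3)
        if (m - h < 0) stop("uniform scenario extends below zero")
        stats::runif(n, m - h, m + h)
      })
  })
}

#' Simulate NEBD timing across a population and dose series
#'
#' Runs [simulate_cell()] for every cell at every PLK1 inhibition dose; the
#' same sampled cdk2-cyclin A activity is reused across doses for a given
#' cell. Cells whose trajectory never reaches the NEBD threshold within
#' `horizon` are censored; per-cell integration failures are recorded as
#' failed rows rather than aborting the sweep.
#'
#' @param scenario a [population_scenario()].
#' @param doses vector of `f_plk1` values; the defaults
#'   `c(1, 0.5, 0.1, 0)` are 0/50/90/100 percent inhibition.
#' @param horizon censoring horizon in hours (default 24, the imaging
#'   window).
#' @param seed integer RNG seed for the activity draws.
#' @param params_fn function `(f_plk1, cyca_cdk2_tot) -> kinetic_params`,
#'   default [default_params()].
#' @param output_step forwarded to [simulate_cell()].
#' @return An `nebd_timing_table` data frame with columns `cell`,
#'   `scenario`, `f_plk1`, `cyca_cdk2_tot`, `nebd_time` (NA when censored
#'   or failed), `censored`, `censor_time`, `failed`.
#' @export
simulate_population <- function(scenario, doses = c(1, 0.5, 0.1, 0),
                                horizon = 24, seed = 1,
                                params_fn = default_params,
                                output_step = 0.05) {
  if (any(doses < 0 | doses > 1)) stop("doses must lie in [0, 1]")
  if (horizon <= 0) stop("horizon must be positive")
  cyca <- sample_population(scenario, seed = seed)
  rows <- vector("list", length(cyca) * length(doses))
  k <- 0
  for (f in doses) {
    for (i in seq_along(cyca)) {
      k <- k + 1
      res <- tryCatch({
        tr <- simulate_cell(params_fn(f_plk1 = f, cyca_cdk2_tot = cyca[i]),
                            horizon = horizon, output_step = output_step,
                            stop_at_nebd = TRUE)
        list(nebd = tr$nebd_time, censored = tr$censored, failed = FALSE)
      }, error = function(e) list(nebd = NA_real_, censored = NA,
                                  failed = TRUE))
      rows[[k]] <- data.frame(
        cell = i, scenario = scenario$name, f_plk1 = f,
        cyca_cdk2_tot = cyca[i], nebd_time = res$nebd,
        censored = res$censored, censor_time = horizon, failed = res$failed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nebd_timing_table", class(out))
  out
}

#' Cumulative fraction of cells having entered mitosis
#'
#' At each grid time, the fraction of cells whose NEBD time is at or before
#' that time, per dose (and scenario); censored and failed cells count in
#' the denominator and never in the numerator.
#'
#' @param table an `nebd_timing_table` from [simulate_population()].
#' @param time_grid increasing vector of query times (h).
#' @return Long data frame: `scenario`, `f_plk1`, `time`, `fraction`.
#' @export
cumulative_entry_curve <- function(table, time_grid) {
  if (length(time_grid) && is.unsorted(time_grid))
    stop("time_grid must be increasing")
  if (nrow(table) == 0)
    return(data.frame(scenario = character(), f_plk1 = numeric(),
                      time = numeric(), fraction = numeric()))
  groups <- unique(table[, c("scenario", "f_plk1")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- table$scenario == groups$scenario[g] &
      table$f_plk1 == groups$f_plk1[g]
    nt <- table$nebd_time[sel]
    n <- sum(sel)
    frac <- vapply(time_grid, function(t) sum(!is.na(nt) & nt <= t) / n, 0)
    data.frame(scenario = groups$scenario[g], f_plk1 = groups$f_plk1[g],
               time = time_grid, fraction = frac)
  })
  do.call(rbind, out)
}

#' Fraction of cells entered by a cut-off time
#'
#' @param table an `nebd_timing_table`.
#' @param t_censor cut-off time (h), at most the table's horizon.
#' @return Data frame `scenario`, `f_plk1`, `fraction`.
#' @export
fraction_entered <- function(table, t_censor) {
  if (nrow(table) && any(t_censor > table$censor_time))
    stop("t_censor exceeds the simulation horizon")
  cc <- cumulative_entry_curve(table, t_censor)
  cc[, c("scenario", "f_plk1", "fraction")]
}

#' Shipped population scenario presets
#'
#' Three regimes of cdk2-cyclin A heterogeneity, read from the package's
#' scenario configuration file: `narrow` (tightly synchronised entry,
#' doses only shift the entry time), `broad` (delays spread out over
#' hours, HeLa-like), and `broad_low` (lowered mean so that at complete
#' PLK1 inhibition most cells fail to enter within 24 h, U2-OS/RPE1-like).
#'
#' @param n_cells cells per scenario (default 400).
#' @return Named list of [population_scenario()] objects.
#' @export
scenario_presets <- function(n_cells = 400) {
  path <- system.file("extdata", "scenarios.json", package = "propro",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(raw), function(nm) {
    b <- raw[[nm]]
    population_scenario(mean = b$mean, sd = b$sd, n_cells = n_cells,
                        distribution = b$distribution, name = nm)
  })
  names(out) <- names(raw)
  out
}
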
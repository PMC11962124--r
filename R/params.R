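#' Kinetic parameters of the mitotic-entry network
#'
#' Builds the full parameter set for the cdk1-cyclin B activation network with
#' a PLK1 input on cdc25. The cdc25 module carries the rate constants of the
#' printed two-state phosphorylation cycle (unphosphorylated / mono- /
#' bi-phosphorylated cdc25); the substrate module carries the cdk1-substrate
#' phosphorylation cycle opposed by PP2A-B55. The remaining network --
#' Tyr15 control of cdk1-cyclin B by cdc25/wee1 and PP2A-B55 inactivation
#' downstream of cdk1 -- is the auxiliary submodel whose constants live in
#' `auxiliary_params`.
#'
#' PLK1 activity is not a state variable: it is an algebraic input
#' `f_plk1 * cyca_cdk2_tot`, so `f_plk1 = 1` is fully active PLK1 and
#' `f_plk1 = 0` complete inhibition.
#'
#' @param k_ppx_y15 constitutive cdc25-phosphatase rate (1/h).
#' @param k_b55_cdc25 PP2A-B55-mediated cdc25 dephosphorylation rate
#'   (1/(a.u. h)).
#' @param k_cdk1_cdc25 cdk1-cyclin B-mediated cdc25 phosphorylation rate
#'   (1/(a.u. h)).
#' @param k_plk1_cdc25 PLK1-mediated cdc25 phosphorylation rate (1/(a.u. h)).
#' @param k_cdk1_sub cdk1 substrate phosphorylation rate (1/(a.u. h)).
#' @param k_b55_sub PP2A-B55 substrate dephosphorylation rate (1/(a.u. h)).
#' @param cdc25_tot,cycbcdk1_tot,sub_tot pool totals (a.u.).
#' @param cyca_cdk2_tot cdk2-cyclin A activity after G2 entry (a.u.).
#' @param f_plk1 PLK1 activity fraction in `[0, 1]`.
#' @param nebd_threshold substrate-phosphorylation fraction declaring NEBD
#'   (default 0.30).
#' @param auxiliary_params named list of auxiliary submodel constants, see
#'   [default_auxiliary_params()].
#' @return An object of class `kinetic_params` (a validated named list).
#' @seealso [default_params()], [network_rhs()], [simulate_cell()]
#' @export
kinetic_params <- function(k_ppx_y15,
                           k_b55_cdc25,
                           k_cdk1_cdc25,
                           k_plk1_cdc25,
                           k_cdk1_sub,
                           k_b55_sub,
                           cdc25_tot,
                           cycbcdk1_tot,
                           sub_tot,
                           cyca_cdk2_tot,
                           f_plk1 = 1,
                           nebd_threshold = 0.30,
                           auxiliary_params = default_auxiliary_params()) {
  p <- list(
    k_ppx_y15 = k_ppx_y15,
    k_b55_cdc25 = k_b55_cdc25,
    k_cdk1_cdc25 = k_cdk1_cdc25,
    k_plk1_cdc25 = k_plk1_cdc25,
    k_cdk1_sub = k_cdk1_sub,
    k_b55_sub = k_b55_sub,
    cdc25_tot = cdc25_tot,
    cycbcdk1_tot = cycbcdk1_tot,
    sub_tot = sub_tot,
    cyca_cdk2_tot = cyca_cdk2_tot,
    f_plk1 = f_plk1,
    nebd_threshold = nebd_threshold,
    auxiliary_params = auxiliary_params
  )
  validate_kinetic_params(p)
  class(p) <- "kinetic_params"
  p
}

rate_names <- c("k_ppx_y15", "k_b55_cdc25", "k_cdk1_cdc25", "k_plk1_cdc25",
                "k_cdk1_sub", "k_b55_sub")
total_names <- c("cdc25_tot", "cycbcdk1_tot", "sub_tot", "cyca_cdk2_tot")
aux_names <- c("k_cdc25_basal", "k_cdc25_act", "k_wee1_basal", "k_wee1_inact",
               "k_wee1_act", "k_b55_wee1", "k_cdk1_wee1", "k_cdk2_wee1",
               "k_b55_act", "k_cdk1_b55", "wee1_tot", "b55_tot")

validate_kinetic_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c(rate_names, total_names)) {
    if (!num1(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("parameter '%s' must be a single non-negative number", nm))
  }
  if (!num1(p$f_plk1) || p$f_plk1 < 0 || p$f_plk1 > 1)
    stop("f_plk1 must lie in [0, 1]")
  if (!num1(p$nebd_threshold) || p$nebd_threshold <= 0 || p$nebd_threshold >= 1)
    stop("nebd_threshold must lie strictly inside (0, 1)")
  ap <- p$auxiliary_params
  if (!is.list(ap) || !all(aux_names %in% names(ap)))
    stop("auxiliary_params must contain: ", paste(aux_names, collapse = ", "))
  for (nm in aux_names) {
    if (!num1(ap[[nm]]) || ap[[nm]] < 0)
      stop(sprintf("auxiliary parameter '%s' must be non-negative", nm))
  }
  invisible(TRUE)
}

#' Default auxiliary submodel constants
#'
#' Constants of the Tyr15/wee1 and PP2A-B55 limbs of the network: activation
#' of cdk1-cyclin B by active (bi-phosphorylated) cdc25 plus a small
#' cdc25pp-independent basal phosphatase activity, inactivation by
#' wee1/myt1; wee1 inactivated by cdk1 (positive feedback) and by
#' cdk2-cyclin A (the PLK1-independent trigger), reactivated by PP2A-B55;
#' PP2A-B55 switched off downstream of cdk1 with the greatwall/ENSA limb
#' collapsed into a single inhibitory step. All first-order rates in 1/h,
#' bimolecular rates in 1/(a.u. h).
#'
#' @return Named list of auxiliary rate constants and pool totals.
#' @export
default_auxiliary_params <- function() {
  list(
    k_cdc25_basal = 0.04,  # basal Tyr15 dephosphorylation of cdk1-cyclin B
    k_cdc25_act   = 4,     # Tyr15 dephosphorylation per unit cdc25pp
    k_wee1_basal  = 0.04,  # wee1-independent cdk1 inactivation
    k_wee1_inact  = 8,     # cdk1 inactivation per unit active wee1
    k_wee1_act    = 1.2,   # basal wee1 reactivation
    k_b55_wee1    = 1.0,   # PP2A-B55 assisted wee1 reactivation
    k_cdk1_wee1   = 12,    # wee1 inactivation per unit active cdk1
    k_cdk2_wee1   = 2.0,   # wee1 inactivation per unit cdk2-cyclin A
    k_b55_act     = 1.6,   # PP2A-B55 reactivation
    k_cdk1_b55    = 12,    # PP2A-B55 inactivation per unit active cdk1
    wee1_tot      = 1,
    b55_tot       = 1
  )
}

#' Default calibrated parameter set
#'
#' The shipped calibration: time unit hours, all pools scaled to 1 a.u.,
#' cdk2-cyclin A activity 4 a.u. after G2 entry. With fully active PLK1
#' (`f_plk1 = 1`) a cell reaches NEBD within roughly an hour of G2 entry;
#' with PLK1 fully inhibited (`f_plk1 = 0`) entry is delayed by several
#' hours, with the substrate-phosphorylation fraction creeping up slowly
#' before the switch flips.
#'
#' @param f_plk1 PLK1 activity fraction.
#' @param cyca_cdk2_tot cdk2-cyclin A activity after G2 entry (a.u.).
#' @return A [kinetic_params()] object.
#' @export
default_params <- function(f_plk1 = 1, cyca_cdk2_tot = 4) {
  kinetic_params(
    k_ppx_y15 = 1.0,
    k_b55_cdc25 = 2.0,
    k_cdk1_cdc25 = 6.0,
    k_plk1_cdc25 = 0.6,
    k_cdk1_sub = 4.0,
    k_b55_sub = 2.0,
    cdc25_tot = 1,
    cycbcdk1_tot = 1,
    sub_tot = 1,
    cyca_cdk2_tot = cyca_cdk2_tot,
    f_plk1 = f_plk1
  )
}

#' Read / write parameter sets as JSON
#'
#' Parameter files hold one or more named blocks, each a full parameter set,
#' so that several scenarios can travel in one file.
#'
#' @param path file path.
#' @return `read_params()`: a named list of [kinetic_params()] objects.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(b) {
    ap <- as.list(b$auxiliary_params)
    b$auxiliary_params <- NULL
    do.call(kinetic_params, c(b, list(auxiliary_params = ap)))
  })
}

#' @rdname read_params
#' @param params a named list of [kinetic_params()] objects (or a single one).
#' @export
write_params <- function(params, path) {
  if (inherits(params, "kinetic_params")) params <- list(default = params)
  blocks <- lapply(params, function(p) unclass(p))
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
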
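## Seeded generators producing inputs with the statistical structure each
## pipeline stage assumes, so every module is testable without downloads.

#' Specification of a synthetic phosphoproteomics experiment
#'
#' Describes a 4-group x 3-replicate TMT design over three sixplex
#' labelling batches (each batch carries one replicate of every group plus
#' pooled reference channels). Site intensities are built additively on the
#' log2 scale: site baseline + batch effect + channel effect + group
#' effects (+ a fixed interaction effect for spiked sites) + noise, with
#' missing-not-at-random dropout applied as a logistic function of the true
#' intensity (low-abundance values drop out preferentially, the mechanism
#' the downshift imputation targets).
#'
#' @param n_sites number of phosphosites.
#' @param interaction_effect log2 effect added to the ProPro cell of spiked
#'   sites (random sign), default 1.
#' @param spike_fraction fraction of sites spiked with the interaction
#'   effect (default 0.05).
#' @param treatment_sd,fraction_sd SDs of per-site random main effects of
#'   the two factors (default 0: pure null apart from spikes).
#' @param within_sd within-group measurement SD in log2 units
#'   (default 0.25).
#' @param batch_sd,channel_sd SDs of batch and channel offsets.
#' @param baseline_mean,baseline_sd distribution of site baselines (log2).
#' @param dropout_midpoint_q quantile of the intensity distribution at
#'   which dropout probability is 50 percent (default 0.15).
#' @param dropout_slope logistic slope per log2 unit (default 2).
#' @param n_ref reference channels per batch (default 2).
#' @param loc_prob_low_fraction,contaminant_fraction,reverse_fraction
#'   fractions of sites given a low localization probability, contaminant
#'   flag, or reverse flag (defaults 0).
#' @param seed integer RNG seed.
#' @return A `phospho_sim_spec` list.
#' @export
phospho_sim_spec <- function(n_sites = 2000, interaction_effect = 1,
                             spike_fraction = 0.05, treatment_sd = 0,
                             fraction_sd = 0, within_sd = 0.25,
                             batch_sd = 0.3, channel_sd = 0.1,
                             baseline_mean = 20, baseline_sd = 1.5,
                             dropout_midpoint_q = 0.15, dropout_slope = 2,
                             n_ref = 2, loc_prob_low_fraction = 0,
                             contaminant_fraction = 0,
                             reverse_fraction = 0, seed = 1) {
  stopifnot(n_sites >= 1, spike_fraction >= 0, spike_fraction <= 1,
            within_sd >= 0, batch_sd >= 0, channel_sd >= 0,
            dropout_midpoint_q >= 0, dropout_midpoint_q <= 1,
            n_ref >= 1)
  structure(as.list(environment()), class = "phospho_sim_spec")
}

#' Generate a synthetic phosphosite table with ground truth
#'
#' @param spec a [phospho_sim_spec()].
#' @return List with `table` (a [phosphosite_table()] with MNAR missing
#'   values) and `truth` (data frame: `site`, `spiked`, `interaction`,
#'   per-site main effects).
#' @export
generate_phospho <- function(spec) {
  stopifnot(inherits(spec, "phospho_sim_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_sites
  ids <- sprintf("site_%05d", seq_len(n))

  ## sample layout: per batch, one replicate of each group + refs
  groups <- factor_groups
  samp <- do.call(rbind, lapply(1:3, function(b) {
    rbind(
      data.frame(sample = sprintf("%s_r%d", groups, b), group = groups,
                 replicate = b, batch = b, is_reference = FALSE),
      data.frame(sample = sprintf("ref%d_b%d", seq_len(spec$n_ref), b),
                 group = NA_character_, replicate = NA_integer_, batch = b,
                 is_reference = TRUE)
    )
  }))

  baseline <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  eff_treat <- stats::rnorm(n, 0, spec$treatment_sd)
  eff_frac <- stats::rnorm(n, 0, spec$fraction_sd)
  n_spike <- round(spec$spike_fraction * n)
  spiked <- logical(n)
  if (n_spike > 0) spiked[sample.int(n, n_spike)] <- TRUE
  inter <- ifelse(spiked,
                  spec$interaction_effect * sample(c(-1, 1), n, TRUE), 0)
  batch_eff <- stats::rnorm(3, 0, spec$batch_sd)
  chan_eff <- stats::rnorm(nrow(samp), 0, spec$channel_sd)

  group_mean <- function(g) {
    tr <- as.numeric(g %in% c("ProPro", "Polo"))     # BI2536
    su <- as.numeric(g %in% c("Prometa", "Polo"))    # suspended
    outer(eff_treat, tr) + outer(eff_frac, su) +
      outer(inter, as.numeric(g == "ProPro"))
  }
  gm <- group_mean(groups)  # n x 4, ordered as factor_groups
  colnames(gm) <- groups

  intens <- matrix(NA_real_, n, nrow(samp),
                   dimnames = list(ids, samp$sample))
  for (j in seq_len(nrow(samp))) {
    mu <- baseline + batch_eff[samp$batch[j]] + chan_eff[j]
    mu <- mu + if (samp$is_reference[j]) rowMeans(gm) else
      gm[, samp$group[j]]
    intens[, j] <- mu + stats::rnorm(n, 0, spec$within_sd)
  }

  ## MNAR dropout: logistic in the true intensity
  midpoint <- stats::quantile(intens, spec$dropout_midpoint_q)
  p_drop <- stats::plogis(-(intens - midpoint) * spec$dropout_slope)
  drop <- matrix(stats::runif(length(intens)) < p_drop, n, nrow(samp))
  intens[drop] <- NA

  loc_prob <- rep(1, n)
  nlow <- round(spec$loc_prob_low_fraction * n)
  if (nlow > 0) loc_prob[sample.int(n, nlow)] <- stats::runif(nlow, 0, 0.74)
  contaminant <- stats::runif(n) < spec$contaminant_fraction
  reverse <- stats::runif(n) < spec$reverse_fraction

  sites <- data.frame(
    id = ids,
    protein = sprintf("P%05d", seq_len(n)),
    gene = sprintf("GENE%d", seq_len(n)),
    residue = sample(c("S", "T", "Y"), n, TRUE, prob = c(0.8, 0.15, 0.05)),
    position = sample.int(2000, n, TRUE),
    loc_prob = loc_prob,
    contaminant = contaminant,
    reverse = reverse,
    multiplicity = sample(1:3, n, TRUE, prob = c(0.7, 0.25, 0.05))
  )
  truth <- data.frame(site = ids, spiked = spiked, interaction = inter,
                      treatment_effect = eff_treat,
                      fraction_effect = eff_frac)
  list(table = phosphosite_table(sites, intens, samp, log2 = TRUE),
       truth = truth)
}

#' Specification of a synthetic labelled movie
#'
#' Nuclei are non-overlapping disks with Gaussian-textured interiors whose
#' relative intensity SD follows `sigma_schedule` (the condensation ramp);
#' the whole signal decays by `exp(-bleach_rate * t)` and sits on a flat
#' background. Label images are exact by construction. NEBD is modelled as
#' disappearance of the label from its event frame onward. Optics (PSF,
#' noise floor structure) are not simulated: the metrics under test are
#' statistics of labelled regions.
#'
#' @param n_nuclei number of nuclei.
#' @param size image side length in pixels.
#' @param radius_range nucleus radius range in pixels.
#' @param sigma_schedule per-frame relative intensity SD inside nuclei; its
#'   length sets the frame count.
#' @param bleach_rate bleaching decay rate per frame (default 0).
#' @param background flat background intensity.
#' @param nucleus_amplitude mean nuclear signal above background.
#' @param cyto_amplitude mean cytoplasmic signal above background
#'   (0 = none); painted on a disk of `cyto_radius` around each nucleus.
#' @param cyto_radius cytoplasm disk radius in pixels.
#' @param nebd_frames per-nucleus NEBD frame indices (NA = no event).
#' @param frame_interval frame interval in minutes.
#' @param seed integer RNG seed.
#' @return A `movie_sim_spec` list.
#' @export
movie_sim_spec <- function(n_nuclei = 5, size = 128,
                           radius_range = c(8, 12),
                           sigma_schedule = seq(0.05, 0.3, length.out = 10),
                           bleach_rate = 0, background = 10,
                           nucleus_amplitude = 100, cyto_amplitude = 0,
                           cyto_radius = 24,
                           nebd_frames = rep(NA_integer_, n_nuclei),
                           frame_interval = 5, seed = 1) {
  stopifnot(n_nuclei >= 0, size >= 16, length(radius_range) == 2,
            radius_range[1] <= radius_range[2],
            all(sigma_schedule >= 0), bleach_rate >= 0,
            length(nebd_frames) == n_nuclei)
  if (2 * radius_range[2] >= size)
    stop("nuclei do not fit the image")
  structure(as.list(environment()), class = "movie_sim_spec")
}

#' Generate a synthetic labelled movie with ground truth
#'
#' @param spec a [movie_sim_spec()].
#' @param max_tries rejection-sampling budget for non-overlapping placement.
#' @return List with `movie` (a [labeled_movie()]) and `truth` (data frame:
#'   nucleus id, centre, radius, NEBD frame).
#' @export
generate_movie <- function(spec, max_tries = 2000) {
  stopifnot(inherits(spec, "movie_sim_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n_frames <- length(spec$sigma_schedule)
  sz <- spec$size

  ## place non-overlapping disks (with clearance for the cytoplasm disk)
  centers <- matrix(NA_real_, spec$n_nuclei, 2)
  radii <- numeric(spec$n_nuclei)
  clearance <- if (spec$cyto_amplitude > 0) spec$cyto_radius else 0
  if (spec$n_nuclei > 0) {
    tries <- 0
    i <- 1
    margin <- max(spec$radius_range[2], clearance) + 1
    while (i <= spec$n_nuclei) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place ", spec$n_nuclei,
             " non-overlapping nuclei; lower the packing")
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      cx <- stats::runif(1, margin, sz - margin)
      cy <- stats::runif(1, margin, sz - margin)
      ok <- TRUE
      if (i > 1) {
        d <- sqrt((centers[1:(i - 1), 1] - cx)^2 +
                  (centers[1:(i - 1), 2] - cy)^2)
        ok <- all(d > radii[1:(i - 1)] + r + 2 * clearance + 2)
      }
      if (ok) {
        centers[i, ] <- c(cx, cy)
        radii[i] <- r
        i <- i + 1
      }
    }
  }

  xg <- matrix(seq_len(sz), sz, sz)
  yg <- t(xg)
  frames <- vector("list", n_frames)
  labels <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    lab <- matrix(0L, sz, sz)
    img <- matrix(spec$background, sz, sz)
    bleach <- exp(-spec$bleach_rate * (t - 1))
    for (i in seq_len(spec$n_nuclei)) {
      if (!is.na(spec$nebd_frames[i]) && t >= spec$nebd_frames[i]) next
      d2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
      if (spec$cyto_amplitude > 0) {
        cy_mask <- d2 <= spec$cyto_radius^2
        img[cy_mask] <- spec$background +
          bleach * spec$cyto_amplitude *
          (1 + spec$sigma_schedule[t] *
             stats::rnorm(sum(cy_mask)))
      }
      mask <- d2 <= radii[i]^2
      lab[mask] <- i
      img[mask] <- spec$background +
        bleach * spec$nucleus_amplitude *
        pmax(0.05, 1 + spec$sigma_schedule[t] * stats::rnorm(sum(mask)))
    }
    frames[[t]] <- img
    labels[[t]] <- lab
  }
  truth <- data.frame(nucleus = seq_len(spec$n_nuclei),
                      x = centers[, 1], y = centers[, 2], radius = radii,
                      nebd_frame = spec$nebd_frames)
  list(movie = labeled_movie(frames, labels, background = spec$background,
                             frame_interval = spec$frame_interval),
       truth = truth)
}
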
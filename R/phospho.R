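## Phosphosite statistics for the 2x2 factorial TMT design.
##
## The four biological states map onto two crossed factors:
##   treatment: DMSO | BI2536 (PLK1 inhibition)
##   fraction:  attached | suspended (pre- vs post-NEBD by shake-off)
## so G2 = DMSO.attached, Prometa = DMSO.suspended, ProPro = BI2536.attached,
## Polo = BI2536.suspended. Three biological replicates are spread over
## three TMT sixplex labelling batches; each batch carries one replicate of
## each state plus pooled reference channels.

factor_groups <- c("G2", "Prometa", "ProPro", "Polo")

group_factors <- function(group) {
  data.frame(
    treatment = ifelse(group %in% c("ProPro", "Polo"), "BI2536", "DMSO"),
    fraction = ifelse(group %in% c("G2", "ProPro"), "attached", "suspended")
  )
}

#' Assemble a phosphosite table
#'
#' @param sites data frame of site metadata with columns `id`, `protein`,
#'   `gene`, `residue`, `position`, `loc_prob`, `contaminant`, `reverse`,
#'   `multiplicity`.
#' @param intensity numeric matrix, one row per site (rownames = `sites$id`),
#'   one column per sample; `NA` marks missing values.
#' @param samples data frame with columns `sample`, `group` (one of
#'   G2/Prometa/ProPro/Polo, or NA for reference channels), `replicate`,
#'   `batch`, `is_reference`.
#' @param log2 is the matrix already log2-transformed?
#' @return A `phosphosite_table` object.
#' @export
phosphosite_table <- function(sites, intensity, samples, log2 = TRUE) {
  need <- c("id", "protein", "gene", "residue", "position", "loc_prob",
            "contaminant", "reverse", "multiplicity")
  if (!all(need %in% names(sites)))
    stop("sites must contain columns: ", paste(need, collapse = ", "))
  needs <- c("sample", "group", "replicate", "batch", "is_reference")
  if (!all(needs %in% names(samples)))
    stop("samples must contain columns: ", paste(needs, collapse = ", "))
  if (nrow(intensity) != nrow(sites) || ncol(intensity) != nrow(samples))
    stop("intensity dimensions must match sites x samples")
  if (any(sites$loc_prob < 0 | sites$loc_prob > 1))
    stop("localization probabilities must lie in [0, 1]")
  key <- paste(sites$id, sites$multiplicity)
  if (anyDuplicated(key)) stop("duplicate (site, multiplicity) keys")
  bad <- !is.na(samples$group) & !(samples$group %in% factor_groups)
  if (any(bad)) stop("unknown sample group(s): ",
                     paste(unique(samples$group[bad]), collapse = ", "))
  rownames(intensity) <- sites$id
  colnames(intensity) <- samples$sample
  structure(list(sites = sites, intensity = intensity, samples = samples,
                 log2 = isTRUE(log2)),
            class = "phosphosite_table")
}

#' @export
print.phosphosite_table <- function(x, ...) {
  cat(sprintf("<phosphosite_table> %d sites x %d samples (%d batches), %s\n",
              nrow(x$sites), nrow(x$samples), length(unique(x$samples$batch)),
              if (x$log2) "log2" else "raw"))
  invisible(x)
}

#' Remove contaminants, reversed hits and poorly localized sites
#'
#' Drops rows flagged as potential contaminants or reversed-sequence
#' decoys, and rows whose phosphogroup localization probability is below
#' `loc_prob_min` (sites exactly at the cutoff are kept: the rule removes
#' probabilities strictly below 0.75).
#'
#' @param table a [phosphosite_table()].
#' @param loc_prob_min minimum localization probability (default 0.75).
#' @return The filtered table.
#' @export
filter_sites <- function(table, loc_prob_min = 0.75) {
  stopifnot(inherits(table, "phosphosite_table"))
  keep <- !table$sites$contaminant & !table$sites$reverse &
    table$sites$loc_prob >= loc_prob_min
  subset_sites(table, keep)
}

subset_sites <- function(table, keep) {
  table$sites <- table$sites[keep, , drop = FALSE]
  table$intensity <- table$intensity[keep, , drop = FALSE]
  table
}

#' Per-batch valid-value filter
#'
#' A site with fewer than `min_valid_fraction` valid (non-missing)
#' intensities among a labelling batch's quantification channels is treated
#' as not quantified in that batch (its values there are masked); sites
#' quantified in no batch are dropped. Reference channels do not count
#' toward the fraction unless `count_reference`.
#'
#' @param table a [phosphosite_table()].
#' @param min_valid_fraction minimum valid fraction per batch (default 0.70).
#' @param count_reference include reference channels in the fraction?
#' @return The filtered table, with an added logical matrix
#'   `attr(, "quantified")` of sites x batches.
#' @export
valid_value_filter <- function(table, min_valid_fraction = 0.70,
                               count_reference = FALSE) {
  stopifnot(inherits(table, "phosphosite_table"))
  batches <- sort(unique(table$samples$batch))
  quant <- matrix(FALSE, nrow(table$sites), length(batches),
                  dimnames = list(table$sites$id, as.character(batches)))
  for (bi in seq_along(batches)) {
    cols <- table$samples$batch == batches[bi]
    if (!count_reference) cols <- cols & !table$samples$is_reference
    sub <- table$intensity[, cols, drop = FALSE]
    frac <- rowMeans(!is.na(sub))
    quant[, bi] <- frac >= min_valid_fraction
    mask_cols <- table$samples$batch == batches[bi]
    table$intensity[!quant[, bi], mask_cols] <- NA
  }
  keep <- rowSums(quant) > 0
  out <- subset_sites(table, keep)
  attr(out, "quantified") <- quant[keep, , drop = FALSE]
  out
}

#' Downshifted-Gaussian imputation of missing intensities
#'
#' Missing (below-detection) values are replaced, per TMT channel/replicate
#' column, by draws from a Gaussian whose mean is shifted down from the
#' column's observed mean by `downshift` observed standard deviations and
#' whose width is `width` observed standard deviations -- the standard
#' treatment of missing-not-at-random low-abundance dropout in proteomics.
#'
#' @param table a [phosphosite_table()] with log2 intensities.
#' @param width imputation width in column-SD units (default 0.3).
#' @param downshift downshift in column-SD units (default 1.8).
#' @param seed integer RNG seed.
#' @return The table with all missing values imputed; imputed positions are
#'   recorded in the logical matrix `attr(, "imputed")`.
#' @export
impute_mnar <- function(table, width = 0.3, downshift = 1.8, seed = 1) {
  stopifnot(inherits(table, "phosphosite_table"))
  if (!table$log2) stop("impute_mnar expects log2-transformed intensities")
  miss <- is.na(table$intensity)
  n_obs <- colSums(!miss)
  if (any(n_obs < 2 & colSums(miss) > 0)) {
    bad <- colnames(table$intensity)[n_obs < 2 & colSums(miss) > 0]
    stop("cannot impute columns with < 2 observed values: ",
         paste(bad, collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (j in seq_len(ncol(table$intensity))) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- table$intensity[!mj, j]
    mu <- mean(obs)
    sdv <- stats::sd(obs)
    table$intensity[mj, j] <- stats::rnorm(sum(mj), mu - downshift * sdv,
                                           width * sdv)
  }
  attr(table, "imputed") <- miss
  table
}

#' Align batches on their pooled reference channels
#'
#' Internal-reference scaling: per batch, the per-site mean of the pooled
#' reference channels is subtracted from every channel of that batch,
#' putting all batches on the scale of the common pool before
#' normalisation. Requires a complete (post-imputation) matrix.
#'
#' @param table a [phosphosite_table()].
#' @return The aligned table.
#' @export
reference_align <- function(table) {
  stopifnot(inherits(table, "phosphosite_table"))
  for (b in unique(table$samples$batch)) {
    refc <- table$samples$batch == b & table$samples$is_reference
    if (!any(refc)) stop("batch ", b, " has no reference channel")
    ref <- rowMeans(table$intensity[, refc, drop = FALSE])
    cols <- table$samples$batch == b
    table$intensity[, cols] <- table$intensity[, cols] - ref
  }
  table
}

#' Per-batch Tukey median-polish normalisation
#'
#' Runs Tukey's median polish (alternating removal of row and column
#' medians) on each labelling batch's complete log2 matrix and subtracts
#' the fitted column (sample) effects from the original values. Row (site)
#' effects are deliberately retained: this is a normalisation, not a
#' decomposition.
#'
#' @param matrix numeric sites x samples matrix, no missing values.
#' @param batch batch assignment, one value per column.
#' @param tol convergence tolerance: after polishing, every residual row
#'   and column median must fall below it (default 1e-3; sweeps over
#'   even-sized tables plateau with row medians of that order).
#' @param max_iter maximum sweep count (default 50).
#' @return List with `normalized` (matrix), `col_effects` (named vector),
#'   `converged` (logical per batch) and `residual_medians` (per batch, the
#'   largest absolute row/column median of the polish residuals).
#' @export
median_polish_normalize <- function(matrix, batch, tol = 1e-3,
                                    max_iter = 50) {
  if (anyNA(matrix)) stop("median polish requires a complete matrix")
  if (length(batch) != ncol(matrix))
    stop("batch must have one value per column")
  out <- matrix
  col_eff <- stats::setNames(numeric(ncol(matrix)), colnames(matrix))
  batches <- unique(batch)
  converged <- stats::setNames(logical(length(batches)),
                               as.character(batches))
  resmed <- stats::setNames(numeric(length(batches)), as.character(batches))
  polishes <- lapply(batches, function(b) {
    stats::medpolish(matrix[, batch == b, drop = FALSE],
                     eps = tol * 1e-4, maxiter = max_iter,
                     trace.iter = FALSE)
  })
  ## a sample's effect is its within-batch column effect plus the batch's
  ## overall level relative to the grand level, so batches land on a common
  ## scale while row (site) effects are retained; with a single batch this
  ## reduces to the plain column effects
  grand <- mean(vapply(polishes, function(mp) mp$overall, 0))
  for (bi in seq_along(batches)) {
    b <- batches[bi]
    cols <- which(batch == b)
    mp <- polishes[[bi]]
    rm_max <- max(abs(apply(mp$residuals, 1, stats::median)),
                  abs(apply(mp$residuals, 2, stats::median)))
    it_ok <- rm_max < tol
    converged[as.character(b)] <- it_ok
    if (!it_ok)
      warning("median polish did not fully converge in batch ", b)
    resmed[as.character(b)] <- rm_max
    col_eff[cols] <- mp$col + mp$overall - grand
    out[, cols] <- sweep(matrix[, cols, drop = FALSE], 2, col_eff[cols])
  }
  list(normalized = out, col_effects = col_eff, converged = converged,
       residual_medians = resmed)
}

#' Least-squares fit of the 2x2 factorial group means
#'
#' Fits, per site, the four group means (the cell-means parameterisation of
#' the treatment x fraction factorial) by least squares, and records the
#' residual variance and degrees of freedom. Reference channels must not
#' appear in the design.
#'
#' @param matrix normalized sites x samples matrix.
#' @param design data frame with a `group` column aligned to the matrix
#'   columns (reference channels removed).
#' @return A `factorial_fit`: list with `coefficients` (sites x 4 matrix of
#'   group means in the order G2, Prometa, ProPro, Polo), `sigma2`, `df`,
#'   `group_n`, `sites` (rownames).
#' @export
fit_factorial <- function(matrix, design) {
  if (nrow(design) != ncol(matrix))
    stop("design must describe every matrix column")
  if (any(is.na(design$group)))
    stop("reference channels must be excluded from the design")
  missing_cells <- setdiff(factor_groups, unique(design$group))
  if (length(missing_cells))
    stop("rank-deficient design, missing group cells: ",
         paste(missing_cells, collapse = ", "))
  n_g <- table(factor(design$group, levels = factor_groups))
  if (any(n_g < 2)) stop("need >= 2 replicates per group")
  ind <- stats::model.matrix(~ 0 + factor(design$group,
                                          levels = factor_groups))
  colnames(ind) <- factor_groups
  coef <- matrix %*% ind %*% diag(1 / as.numeric(n_g))
  colnames(coef) <- factor_groups
  fitted <- coef %*% t(ind)
  rss <- rowSums((matrix - fitted)^2)
  d <- ncol(matrix) - length(factor_groups)
  structure(list(coefficients = coef, sigma2 = rss / d, df = d,
                 group_n = as.numeric(n_g), sites = rownames(matrix)),
            class = "factorial_fit")
}

## Newton inversion of the trigamma function (for the prior df estimate)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of the residual variances
#'
#' Borrows strength across sites by fitting a scaled-F prior to the
#' residual variances: matching the mean and variance of `log(s^2)` to the
#' theoretical log-F moments (digamma/trigamma) yields the prior degrees of
#' freedom `d0` and prior variance `s0^2`; each site's variance is then
#' shrunk to \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)} and the
#' moderated t statistics gain `d0` degrees of freedom. When the observed
#' variances carry no excess spread over the sampling noise, `d0` is
#' infinite and every site gets `s0^2`.
#'
#' @param fit a `factorial_fit` from [fit_factorial()].
#' @return The fit with added `s2_post`, `d0`, `s02`.
#' @export
moderate_variances <- function(fit) {
  stopifnot(inherits(fit, "factorial_fit"))
  if (length(fit$sigma2) < 10)
    warning("fewer than 10 sites: hyperparameter estimates are unstable")
  s2 <- fit$sigma2
  d <- fit$df
  ok <- s2 > 0
  if (!any(ok)) { # degenerate: all residuals exactly zero
    fit$d0 <- Inf; fit$s02 <- 0; fit$s2_post <- rep(0, length(s2))
    return(fit)
  }
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (length(e) > 1 && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
  }
  fit$d0 <- d0
  fit$s02 <- s02
  fit$s2_post <- s2_post
  fit
}

## shared contrast machinery: L is a named weight vector over the groups
contrast_table <- function(fit, L, name) {
  if (is.null(fit$s2_post))
    stop("run moderate_variances() before extracting contrasts")
  lfc <- as.numeric(fit$coefficients %*% L)
  vf <- sum(L^2 / fit$group_n)
  df_total <- fit$df + fit$d0
  tstat <- lfc / sqrt(fit$s2_post * vf)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(site = fit$sites, contrast = name, log2fc = lfc,
             t = tstat, p = p, adj_p = bh_adjust(p))
}

#' Prolonged-prophase interaction contrast
#'
#' The factorial interaction
#' `[BI2536.attached - BI2536.suspended] - [DMSO.attached - DMSO.suspended]`
#' (= `(ProPro - Polo) - (G2 - Prometa)`) isolates phosphosites whose
#' response to PLK1 inhibition is specific to the pre-NEBD, attached state:
#' effects shared by both PLK1-inhibited states, and effects shared by both
#' pre-NEBD states, cancel.
#'
#' @param fit a moderated `factorial_fit`.
#' @return Data frame with `site`, `log2fc`, moderated `t`, `p` and
#'   BH-adjusted `adj_p`.
#' @export
interaction_contrast <- function(fit) {
  L <- c(G2 = -1, Prometa = 1, ProPro = 1, Polo = -1)
  contrast_table(fit, L, "ProPro_interaction")
}

#' The four pairwise edges of the factorial square
#'
#' Prometa vs G2 and Polo vs ProPro (mitotic entry with and without PLK1),
#' ProPro vs G2 and Polo vs Prometa (PLK1 inhibition before and after
#' NEBD), each with moderated statistics and BH adjustment within the
#' contrast.
#'
#' @param fit a moderated `factorial_fit`.
#' @return Named list of four contrast data frames.
#' @export
pairwise_contrasts <- function(fit) {
  defs <- list(
    Prometa_vs_G2 = c(G2 = -1, Prometa = 1, ProPro = 0, Polo = 0),
    Polo_vs_ProPro = c(G2 = 0, Prometa = 0, ProPro = -1, Polo = 1),
    ProPro_vs_G2 = c(G2 = -1, Prometa = 0, ProPro = 1, Polo = 0),
    Polo_vs_Prometa = c(G2 = 0, Prometa = -1, ProPro = 0, Polo = 1)
  )
  lapply(stats::setNames(names(defs), names(defs)),
         function(nm) contrast_table(fit, defs[[nm]], nm))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p_values numeric p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify contrast hits
#'
#' Significance requires adjusted p below `p_cut` (default 0.05) and
#' |log2 fold change| above `lfc_cut`; direction follows the sign of the
#' fold change. With the default `lfc_cut = 0` the up/down split is by
#' sign only; the volcano-style classification uses `lfc_cut = 0.5`.
#'
#' @param contrast_table a contrast data frame (`log2fc`, `adj_p`).
#' @param p_cut adjusted-p cutoff (default 0.05).
#' @param lfc_cut absolute log2-fold-change cutoff (default 0).
#' @return The table with an added `class` column in {up, down, ns}.
#' @export
classify_hits <- function(contrast_table, p_cut = 0.05, lfc_cut = 0) {
  sig <- contrast_table$adj_p < p_cut & abs(contrast_table$log2fc) > lfc_cut
  contrast_table$class <- ifelse(!sig, "ns",
                                 ifelse(contrast_table$log2fc > 0, "up",
                                        "down"))
  contrast_table
}

#' Run the full phosphosite pipeline
#'
#' Chains site filtering, the per-batch valid-value rule, downshifted
#' imputation, optional reference-channel alignment, per-batch median
#' polish, the factorial fit, variance moderation, and the interaction plus
#' pairwise contrasts.
#'
#' @param table a raw [phosphosite_table()].
#' @param loc_prob_min,min_valid_fraction,width,downshift,p_cut,lfc_cut
#'   stage parameters (see the individual stage functions).
#' @param align_reference subtract the pooled-reference profile per batch
#'   before normalisation? Off by default: column-level batch effects are
#'   already absorbed by the per-batch median polish, and with few
#'   reference channels the per-site subtraction injects correlated noise
#'   that inflates residual variances; enable it when site-level batch
#'   effects (e.g. batch-specific interference) are expected to dominate
#'   that cost.
#' @param seed RNG seed for the imputation draws.
#' @return List with the processed `table`, the `fit`, `interaction`
#'   (classified contrast table), `pairwise` (list of classified tables),
#'   `normalization` (median-polish report) and the parameter set used.
#' @export
phospho_pipeline <- function(table, loc_prob_min = 0.75,
                             min_valid_fraction = 0.70, width = 0.3,
                             downshift = 1.8, align_reference = FALSE,
                             p_cut = 0.05, lfc_cut = 0, seed = 1) {
  tab <- filter_sites(table, loc_prob_min)
  tab <- valid_value_filter(tab, min_valid_fraction)
  tab <- impute_mnar(tab, width = width, downshift = downshift, seed = seed)
  if (align_reference) tab <- reference_align(tab)
  np <- median_polish_normalize(tab$intensity, tab$samples$batch)
  tab$intensity <- np$normalized
  quant_cols <- !tab$samples$is_reference
  fit <- fit_factorial(tab$intensity[, quant_cols, drop = FALSE],
                       tab$samples[quant_cols, , drop = FALSE])
  fit <- moderate_variances(fit)
  list(table = tab,
       fit = fit,
       interaction = classify_hits(interaction_contrast(fit), p_cut,
                                   lfc_cut),
       pairwise = lapply(pairwise_contrasts(fit), classify_hits,
                         p_cut = p_cut, lfc_cut = lfc_cut),
       normalization = np,
       parameters = list(loc_prob_min = loc_prob_min,
                         min_valid_fraction = min_valid_fraction,
                         width = width, downshift = downshift,
                         align_reference = align_reference, p_cut = p_cut,
                         lfc_cut = lfc_cut, seed = seed))
}
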
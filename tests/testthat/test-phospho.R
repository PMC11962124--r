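make_table <- function(sites, intensity, samples) {
  phosphosite_table(sites, intensity, samples, log2 = TRUE)
}

single_batch_samples <- function(n, batch = 1) {
  data.frame(sample = sprintf("b%d_c%02d", batch, seq_len(n)),
             group = rep(c("G2", "Prometa", "ProPro", "Polo"),
                         length.out = n),
             replicate = 1L, batch = batch, is_reference = FALSE)
}

test_that("site filtering applies the localization and decoy rules", {
  sites <- toy_sites(5)
  sites$loc_prob <- c(0.9, 0.74, 0.75, 0.8, 0.8)
  sites$contaminant <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  sites$reverse <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  samp <- single_batch_samples(4)
  tab <- make_table(sites, matrix(20, 5, 4), samp)
  out <- filter_sites(tab)
  # the 0.75 boundary site survives: the rule removes probabilities < 0.75
  expect_equal(out$sites$id, c("s001", "s003"))
  empty <- filter_sites(make_table(sites[0, ], matrix(0, 0, 4), samp))
  expect_equal(nrow(empty$sites), 0)
})

test_that("valid-value rule is applied per labelling batch", {
  # one batch of 18 quantification channels: 12/18 = 66.7% is dropped,
  # 13/18 = 72.2% is kept
  samp <- single_batch_samples(18)
  m <- matrix(20, 2, 18)
  m[1, 1:6] <- NA    # 12 valid
  m[2, 1:5] <- NA    # 13 valid
  tab <- make_table(toy_sites(2), m, samp)
  out <- valid_value_filter(tab, min_valid_fraction = 0.70)
  expect_equal(out$sites$id, "s002")

  # a site below threshold in one batch but fine in another is masked
  # there and kept overall
  samp2 <- rbind(single_batch_samples(4, 1), single_batch_samples(4, 2))
  samp2$sample <- sprintf("c%02d", 1:8)
  m2 <- matrix(20, 1, 8)
  m2[1, 1:2] <- NA   # batch 1: 2/4 valid -> masked; batch 2 complete
  tab2 <- make_table(toy_sites(1), m2, samp2)
  out2 <- valid_value_filter(tab2, 0.70)
  expect_equal(nrow(out2$sites), 1)
  expect_true(all(is.na(out2$intensity[1, 1:4])))
  expect_false(anyNA(out2$intensity[1, 5:8]))
  expect_equal(unname(attr(out2, "quantified")[1, ]), c(FALSE, TRUE))

  # fully observed sites pass untouched
  full <- make_table(toy_sites(1), matrix(20, 1, 8), samp2)
  expect_equal(nrow(valid_value_filter(full)$sites), 1)
})

test_that("imputation reproduces the downshift and width as standardized moments", {
  n_obs <- 1e5
  n_mis <- 1e4
  set.seed(202)
  obs <- stats::rnorm(n_obs, 20, 1)
  m <- matrix(c(obs, rep(NA_real_, n_mis)), ncol = 1)
  samp <- single_batch_samples(1)
  tab <- make_table(toy_sites(n_obs + n_mis), m, samp)
  out <- impute_mnar(tab, width = 0.3, downshift = 1.8, seed = 5)
  expect_false(anyNA(out$intensity))
  imp <- out$intensity[attr(out, "imputed")[, 1], 1]
  mu_obs <- mean(obs)
  sd_obs <- stats::sd(obs)
  # Monte-Carlo moments: downshift 1.8 column SDs, width 0.3 column SDs
  expect_equal((mu_obs - mean(imp)) / sd_obs, 1.8, tolerance = 0.01)
  expect_equal(stats::sd(imp) / sd_obs, 0.3, tolerance = 0.02)

  # no missing values: table unchanged
  comp <- make_table(toy_sites(3), matrix(20, 3, 1), samp)
  expect_equal(impute_mnar(comp, seed = 1)$intensity, comp$intensity)
  # a column with < 2 observed values cannot be imputed
  bad <- make_table(toy_sites(3), matrix(c(20, NA, NA), 3, 1), samp)
  expect_error(impute_mnar(bad, seed = 1), "< 2 observed")
})

test_that("imputation is reproducible under its seed", {
  g <- generate_phospho(phospho_sim_spec(n_sites = 200, seed = 4))
  a <- impute_mnar(g$table, seed = 9)
  b <- impute_mnar(g$table, seed = 9)
  expect_identical(a$intensity, b$intensity)
})

test_that("median polish normalisation reproduces the worked 3x3 example", {
  m <- matrix(1:9, 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("c", 1:3)))
  out <- median_polish_normalize(m, batch = rep(1, 3))
  expect_equal(unname(out$col_effects), c(-1, 0, 1))
  expect_equal(unname(out$normalized),
               matrix(c(2, 2, 2, 5, 5, 5, 8, 8, 8), 3, 3, byrow = TRUE))
  expect_true(all(out$converged))

  # already-polished matrix: unchanged with zero column effects
  z <- matrix(c(0, 1, -1, 0, 1, -1, 0, 1, -1), 3, 3)
  outz <- median_polish_normalize(z, batch = rep(1, 3))
  expect_equal(unname(outz$col_effects), c(0, 0, 0))
  expect_equal(outz$normalized, z)

  expect_error(median_polish_normalize(matrix(c(1, NA), 1, 2), c(1, 1)),
               "complete")
  expect_error(median_polish_normalize(m, batch = 1), "per column")
})

test_that("per-batch polish leaves residual medians near zero and aligns batches", {
  g <- generate_phospho(phospho_sim_spec(n_sites = 400, seed = 12))
  tab <- impute_mnar(valid_value_filter(g$table), seed = 12)
  out <- median_polish_normalize(tab$intensity, tab$samples$batch)
  expect_true(all(out$residual_medians < 1e-3))
  # after additionally sweeping out row (site) effects, every column of
  # every batch is centred: the polish decomposition is exhausted
  for (b in 1:3) {
    sub <- out$normalized[, tab$samples$batch == b]
    resid <- sweep(sub, 1, apply(sub, 1, stats::median))
    expect_lt(max(abs(apply(resid, 2, stats::median))), 1e-3)
  }
})

test_that("factorial fit recovers group means with closed-form least squares", {
  means <- list(G2 = 10, Prometa = 12, ProPro = 11, Polo = 9)
  d <- toy_phospho_matrix(5, means, sd = 0)
  fit <- fit_factorial(d$matrix, d$design)
  expect_equal(unname(fit$coefficients[1, ]), c(10, 12, 11, 9))
  expect_equal(unname(fit$sigma2), rep(0, 5))
  expect_equal(fit$df, 8)

  # with noise, the coefficients equal the per-group sample means
  dn <- toy_phospho_matrix(3, means, sd = 0.5, seed = 8)
  fitn <- fit_factorial(dn$matrix, dn$design)
  for (g in c("G2", "Prometa", "ProPro", "Polo")) {
    expect_equal(unname(fitn$coefficients[, g]),
                 unname(rowMeans(dn$matrix[, dn$design$group == g])))
  }

  miss <- d$design$group != "Polo"
  expect_error(fit_factorial(d$matrix[, miss], d$design[miss, ]), "Polo")
  refd <- d$design
  refd$group[1] <- NA
  expect_error(fit_factorial(d$matrix, refd), "reference")
})

test_that("variance moderation matches the shrinkage formula and limma", {
  skip_if_not_installed("limma")
  set.seed(31)
  means <- list(G2 = 10, Prometa = 10, ProPro = 10, Polo = 10)
  d <- toy_phospho_matrix(300, means, sd = 0.4, seed = 31)
  # heterogeneous variances so the prior df is finite
  scale <- sqrt(stats::rchisq(300, df = 5) / 5)
  d$matrix <- d$matrix * scale + 10 * (1 - scale)
  fit <- moderate_variances(fit_factorial(d$matrix, d$design))
  sq <- limma::squeezeVar(fit$sigma2, df = fit$df)
  expect_equal(fit$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, sq$var.prior, tolerance = 1e-6)
  expect_equal(fit$s2_post, sq$var.post, tolerance = 1e-6)
  # shrinkage lands between the site variance and the prior
  lo <- pmin(fit$sigma2, fit$s02)
  hi <- pmax(fit$sigma2, fit$s02)
  expect_true(all(fit$s2_post >= lo - 1e-12 & fit$s2_post <= hi + 1e-12))
  # explicit arithmetic: s2 = 2, d = 4, d0 = 4, s02 = 1 -> 1.5
  expect_equal((4 * 1 + 4 * 2) / (4 + 4), 1.5)
  expect_equal(unname((fit$d0 * fit$s02 + fit$df * fit$sigma2) /
                        (fit$d0 + fit$df)),
               unname(fit$s2_post))
})

test_that("identical residual variances hit the infinite-prior branch", {
  means <- list(G2 = 10, Prometa = 10, ProPro = 10, Polo = 10)
  d <- toy_phospho_matrix(20, means, sd = 0)
  fit <- suppressWarnings(moderate_variances(fit_factorial(d$matrix,
                                                           d$design)))
  expect_true(is.infinite(fit$d0))
})

test_that("interaction contrast isolates the ProPro-specific difference", {
  # means (BI.att, BI.susp, DMSO.att, DMSO.susp) = (10, 7, 9, 9) -> 3
  means <- list(ProPro = 10, Polo = 7, G2 = 9, Prometa = 9)
  d <- toy_phospho_matrix(12, means, sd = 1e-4, seed = 2)
  fit <- moderate_variances(fit_factorial(d$matrix, d$design))
  ic <- interaction_contrast(fit)
  expect_equal(ic$log2fc, rep(3, 12), tolerance = 1e-3)

  # equal group means: zero contrast everywhere
  eq <- toy_phospho_matrix(12, list(G2 = 5, Prometa = 5, ProPro = 5,
                                   Polo = 5), sd = 1e-4, seed = 3)
  fe <- moderate_variances(fit_factorial(eq$matrix, eq$design))
  expect_equal(interaction_contrast(fe)$log2fc, rep(0, 12),
               tolerance = 1e-3)
})

test_that("pairwise contrasts carry the expected signs on a spiked site", {
  means <- list(G2 = 10, Prometa = 14, ProPro = 11, Polo = 13)
  d <- toy_phospho_matrix(12, means, sd = 1e-4, seed = 5)
  fit <- moderate_variances(fit_factorial(d$matrix, d$design))
  pw <- pairwise_contrasts(fit)
  expect_named(pw, c("Prometa_vs_G2", "Polo_vs_ProPro", "ProPro_vs_G2",
                     "Polo_vs_Prometa"))
  expect_equal(pw$Prometa_vs_G2$log2fc[1], 4, tolerance = 1e-3)
  expect_equal(pw$Polo_vs_ProPro$log2fc[1], 2, tolerance = 1e-3)
  expect_equal(pw$ProPro_vs_G2$log2fc[1], 1, tolerance = 1e-3)
  expect_equal(pw$Polo_vs_Prometa$log2fc[1], -1, tolerance = 1e-3)
})

test_that("pairwise p-values are approximately uniform under the null", {
  g <- generate_phospho(phospho_sim_spec(n_sites = 800, spike_fraction = 0,
                                         dropout_midpoint_q = 0,
                                         dropout_slope = 50, seed = 21))
  res <- suppressWarnings(phospho_pipeline(g$table, seed = 21))
  # four simultaneous checks: demand calibrated tail mass per contrast and
  # no gross departure from uniformity overall
  for (ct in res$pairwise) {
    expect_gt(stats::ks.test(ct$p, "punif")$p.value, 1e-4)
    expect_lt(abs(mean(ct$p < 0.05) - 0.05), 0.03)
    expect_lt(abs(mean(ct$p) - 0.5), 0.05)
  }
})

test_that("BH adjustment reproduces the step-up worked example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.2, 0.8, 0.03, 0.5)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit classification follows the p and fold-change rules", {
  tab <- data.frame(site = letters[1:4],
                    log2fc = c(0.8, -0.8, 2, 0.3),
                    adj_p = c(0.01, 0.01, 0.2, 0.01))
  out <- classify_hits(tab, p_cut = 0.05, lfc_cut = 0.5)
  expect_equal(out$class, c("up", "down", "ns", "ns"))
  # sign-only classification used for the factorial-square counts
  out0 <- classify_hits(tab, p_cut = 0.05, lfc_cut = 0)
  expect_equal(out0$class, c("up", "down", "ns", "up"))
})

test_that("the pipeline is deterministic under a fixed seed", {
  g <- generate_phospho(phospho_sim_spec(n_sites = 300, seed = 14))
  r1 <- suppressWarnings(phospho_pipeline(g$table, seed = 14))
  r2 <- suppressWarnings(phospho_pipeline(g$table, seed = 14))
  expect_identical(r1$interaction, r2$interaction)
  expect_identical(lapply(r1$pairwise, `[[`, "p"),
                   lapply(r2$pairwise, `[[`, "p"))
})

test_that("moderated p-values agree with a limma fit of the same design", {
  skip_if_not_installed("limma")
  g <- generate_phospho(phospho_sim_spec(n_sites = 400, seed = 17,
                                         dropout_midpoint_q = 0,
                                         dropout_slope = 50))
  res <- suppressWarnings(phospho_pipeline(g$table, seed = 17))
  tab <- res$table
  qc <- !tab$samples$is_reference
  m <- tab$intensity[, qc]
  grp <- factor(tab$samples$group[qc],
                levels = c("G2", "Prometa", "ProPro", "Polo"))
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  lf <- limma::lmFit(m, X)
  ct <- limma::makeContrasts((ProPro - Polo) - (G2 - Prometa), levels = X)
  lf2 <- limma::eBayes(limma::contrasts.fit(lf, ct))
  tt <- limma::topTable(lf2, number = Inf, sort.by = "none")
  expect_equal(res$interaction$log2fc,
               unname(tt$logFC[match(res$interaction$site, rownames(m))]),
               tolerance = 1e-9)
  expect_equal(res$interaction$p,
               unname(tt$P.Value[match(res$interaction$site, rownames(m))]),
               tolerance = 1e-3)
})

test_that("reference alignment subtracts the per-batch pooled profile", {
  g <- generate_phospho(phospho_sim_spec(n_sites = 50, seed = 6))
  tab <- impute_mnar(g$table, seed = 6)
  al <- reference_align(tab)
  refc <- tab$samples$batch == 1 & tab$samples$is_reference
  ref <- rowMeans(tab$intensity[, refc])
  cols <- tab$samples$batch == 1
  expect_equal(al$intensity[, cols], tab$intensity[, cols] - ref)
  # after alignment, the references of each batch average to zero per site
  expect_equal(unname(rowMeans(al$intensity[, refc])), rep(0, 50))
})
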
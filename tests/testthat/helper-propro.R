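# shared fixtures, all built in code

# parameters for exercising the printed cdc25 / substrate equations in
# isolation (reduced mode): rates chosen for hand-checkable arithmetic
toy_params <- function(...) {
  args <- list(...)
  base <- list(k_ppx_y15 = 1, k_b55_cdc25 = 2, k_cdk1_cdc25 = 1,
               k_plk1_cdc25 = 1, k_cdk1_sub = 1, k_b55_sub = 1,
               cdc25_tot = 1, cycbcdk1_tot = 1, sub_tot = 1,
               cyca_cdk2_tot = 2, f_plk1 = 1)
  base[names(args)] <- args
  do.call(kinetic_params, base)
}

# minimal valid site metadata frame
toy_sites <- function(n, loc_prob = 1, contaminant = FALSE,
                      reverse = FALSE) {
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    protein = sprintf("P%03d", seq_len(n)),
    gene = sprintf("G%d", seq_len(n)),
    residue = "S",
    position = seq_len(n),
    loc_prob = rep_len(loc_prob, n),
    contaminant = rep_len(contaminant, n),
    reverse = rep_len(reverse, n),
    multiplicity = 1L
  )
}

# balanced 4-group x 3-replicate design over 3 batches, no reference
# channels, with the supplied per-group true means and noise sd
toy_phospho_matrix <- function(n_sites, group_means, sd = 0, seed = 1) {
  set.seed(seed)
  samp <- expand.grid(group = c("G2", "Prometa", "ProPro", "Polo"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  samp$sample <- paste0(samp$group, "_r", samp$replicate)
  samp$batch <- samp$replicate
  samp$is_reference <- FALSE
  m <- matrix(0, n_sites, nrow(samp),
              dimnames = list(sprintf("s%03d", seq_len(n_sites)),
                              samp$sample))
  for (j in seq_len(nrow(samp)))
    m[, j] <- group_means[[samp$group[j]]] + stats::rnorm(n_sites, 0, sd)
  list(matrix = m, design = samp)
}

# filled-disk mask/image builders for the imaging metrics
disk_mask <- function(size, cx, cy, r) {
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}

ellipse_mask <- function(size, cx, cy, a, b) {
  xg <- matrix(seq_len(size), size, size)
  yg <- t(xg)
  ((xg - cx) / a)^2 + ((yg - cy) / b)^2 <= 1
}
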
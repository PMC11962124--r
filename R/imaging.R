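## Per-nucleus and per-cell quantification metrics for label + intensity
## movies. Segmentation and tracking are consumed as inputs (integer label
## images, track tables), not computed here.
##
## Conventions: frames are matrices indexed [row, col] with origin at the
## top-left; label images use 0 for background and positive integers for
## nuclei; frame indices are 1-based in R, exports keep that convention.

#' Assemble a labelled movie
#'
#' @param frames list (over time) of 2D intensity matrices, one channel.
#' @param labels list of integer label matrices aligned to `frames`
#'   (0 = background).
#' @param background global background intensity.
#' @param frame_interval frame interval in minutes.
#' @param z_stacks optional list of 3D arrays (x, y, z) per frame.
#' @return A `labeled_movie` object.
#' @export
labeled_movie <- function(frames, labels, background = 0,
                          frame_interval = 5, z_stacks = NULL) {
  if (length(frames) != length(labels))
    stop("frames and labels must have the same length")
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), dim(labels[[i]])))
      stop("frame and label shapes differ at frame ", i)
    if (any(labels[[i]] < 0) || any(labels[[i]] != round(labels[[i]])))
      stop("labels must be non-negative integers")
  }
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(frames = frames, labels = labels, background = background,
                 frame_interval = frame_interval, z_stacks = z_stacks),
            class = "labeled_movie")
}

#' Filter a label image by area and border contact
#'
#' Removes labels smaller than `min_area` pixels (default 1000, matching
#' typical nucleus sizes at 2x-downsampled 20x acquisition) and, when
#' `drop_border`, labels touching any image edge.
#'
#' @param label_image integer label matrix.
#' @param min_area minimum pixel area (default 1000).
#' @param drop_border drop labels touching the border (default TRUE)?
#' @return The filtered label image.
#' @export
filter_labels <- function(label_image, min_area = 1000, drop_border = TRUE) {
  ids <- setdiff(unique(as.vector(label_image)), 0)
  if (!length(ids)) return(label_image)
  drop <- numeric(0)
  for (id in ids) {
    m <- label_image == id
    if (sum(m) < min_area) { drop <- c(drop, id); next }
    if (drop_border) {
      touches <- any(m[1, ]) || any(m[nrow(m), ]) ||
        any(m[, 1]) || any(m[, ncol(m)])
      if (touches) drop <- c(drop, id)
    }
  }
  label_image[label_image %in% drop] <- 0
  label_image
}

#' Chromosome-condensation score of one nucleus
#'
#' The population standard deviation of the nucleus' pixel intensities
#' divided by its background-corrected mean. The division makes the score
#' invariant to multiplicative intensity changes (bleaching), so no
#' separate bleaching correction is applied; condensing chromatin raises
#' the score by concentrating signal into fewer, brighter pixels.
#'
#' @param pixels intensity values of the nucleus' pixels.
#' @param background global background intensity.
#' @return Dimensionless score.
#' @export
condensation_score <- function(pixels, background = 0) {
  m <- mean(pixels)
  if (!(m > background))
    stop("undefined condensation score: mean intensity <= background")
  n <- length(pixels)
  sd_pop <- sqrt(sum((pixels - m)^2) / n)
  sd_pop / (m - background)
}

#' Condensation score of every nucleus in every frame
#'
#' @param movie a [labeled_movie()].
#' @param min_area,drop_border forwarded to [filter_labels()].
#' @return Long data frame: `frame`, `label`, `score`.
#' @export
condensation_course <- function(movie, min_area = 0, drop_border = FALSE) {
  rows <- list()
  for (t in seq_along(movie$frames)) {
    lab <- filter_labels(movie$labels[[t]], min_area, drop_border)
    for (id in setdiff(unique(as.vector(lab)), 0)) {
      px <- movie$frames[[t]][lab == id]
      rows[[length(rows) + 1]] <- data.frame(
        frame = t, label = id,
        score = condensation_score(px, movie$background))
    }
  }
  if (!length(rows)) return(data.frame(frame = integer(), label = integer(),
                                       score = numeric()))
  do.call(rbind, rows)
}

## Voronoi territory of each nucleus: every pixel is assigned to the label
## whose nearest nucleus pixel is closest (Euclidean), ties to the lower id
voronoi_territories <- function(labels) {
  ids <- setdiff(unique(as.vector(labels)), 0)
  if (!length(ids)) return(labels)
  dist_to <- lapply(ids, function(id) {
    EBImage::distmap(ifelse(labels == id, 0, 1))
  })
  terr <- matrix(ids[1], nrow(labels), ncol(labels))
  best <- dist_to[[1]]
  for (k in seq_along(ids)[-1]) {
    closer <- dist_to[[k]] < best
    terr[closer] <- ids[k]
    best[closer] <- dist_to[[k]][closer]
  }
  terr
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' The cytoplasm of a nucleus is approximated by the ring obtained by
#' dilating its label with a disk of `dilation_radius` pixels, clipping to
#' the nucleus' Voronoi territory with respect to the other nuclei, and
#' subtracting the nucleus itself. Returns the ratio of background-
#' subtracted mean intensities.
#'
#' @param frame intensity matrix.
#' @param labels integer label matrix.
#' @param nucleus label id of the nucleus.
#' @param dilation_radius ring radius in pixels (default 10).
#' @param background global background intensity.
#' @return List with `ratio`, `nuclear_mean`, `ring_mean` (both
#'   background-subtracted).
#' @export
nc_ratio <- function(frame, labels, nucleus, dilation_radius = 10,
                     background = 0) {
  mask <- labels == nucleus
  if (!any(mask)) stop("nucleus ", nucleus, " not present in labels")
  brush <- EBImage::makeBrush(2 * dilation_radius + 1, shape = "disc")
  dil <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
  terr <- voronoi_territories(labels)
  ring <- dil & !mask & terr == nucleus & labels == 0
  if (!any(ring)) stop("empty cytoplasmic ring for nucleus ", nucleus)
  nuc_mean <- mean(frame[mask]) - background
  ring_mean <- mean(frame[ring]) - background
  if (ring_mean <= 0) stop("undefined N/C ratio: ring mean <= background")
  list(ratio = nuc_mean / ring_mean, nuclear_mean = nuc_mean,
       ring_mean = ring_mean)
}

#' Normalize a series to its early-frame baseline
#'
#' Divides a per-frame series by its mean over the first `n` frames, the
#' convention used for cytoplasmic intensity and z-centroid time courses.
#'
#' @param series numeric vector.
#' @param n baseline length in frames (default 5).
#' @return The normalized series.
#' @export
normalize_first_frames <- function(series, n = 5) {
  if (length(series) < n) stop("series shorter than the baseline window")
  base <- mean(series[seq_len(n)])
  if (!is.finite(base) || base == 0) stop("undefined baseline mean")
  series / base
}

#' FRET ratio from background-corrected channel means
#'
#' @param yfp_mean,cfp_mean per-nucleus mean intensities of the acceptor
#'   (YFP) and donor (CFP) channels; vectors give a per-frame series.
#' @param yfp_bg,cfp_bg channel backgrounds.
#' @return `(yfp_mean - yfp_bg) / (cfp_mean - cfp_bg)`.
#' @export
fret_ratio <- function(yfp_mean, cfp_mean, yfp_bg = 0, cfp_bg = 0) {
  den <- cfp_mean - cfp_bg
  if (any(den <= 0)) stop("undefined FRET ratio: corrected CFP <= 0")
  (yfp_mean - yfp_bg) / den
}

## eccentricity of the second-moments ellipse of a binary mask
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("mask too small for an ellipse fit")
  cc <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  ev <- sort(eigen(cc, only.values = TRUE)$values, decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Cell-outline eccentricity time course, normalized after NEBD
#'
#' Computes the per-frame eccentricity of the (cell-outline) masks and
#' divides the series by its mean over the frames within `window_min`
#' minutes after NEBD (2 frames at the default 5-min interval). Rounding
#' up, a cell's outline becomes circular and its normalized eccentricity
#' falls toward 1 at NEBD. If the normalization window mean is nearly zero
#' (near-circular post-NEBD outline) the unnormalized series is returned
#' with `status = "unnormalized"`.
#'
#' @param masks list of per-frame logical masks.
#' @param nebd_frame 1-based frame index of NEBD.
#' @param frame_interval frame interval in minutes (default 5).
#' @param window_min normalization window after NEBD in minutes
#'   (default 10).
#' @return List with `eccentricity` (normalized series), `raw`, `status`.
#' @export
eccentricity_course <- function(masks, nebd_frame, frame_interval = 5,
                                window_min = 10) {
  if (nebd_frame < 1 || nebd_frame > length(masks))
    stop("nebd_frame outside the series")
  raw <- vapply(masks, mask_eccentricity, 0)
  n_after <- max(1, floor(window_min / frame_interval))
  win <- seq(nebd_frame + 1, min(length(masks), nebd_frame + n_after))
  base <- mean(raw[win])
  if (!is.finite(base) || base < 1e-6)
    return(list(eccentricity = raw, raw = raw, status = "unnormalized"))
  list(eccentricity = raw / base, raw = raw, status = "normalized")
}

#' Intensity-weighted z centroid of a masked stack
#'
#' Within the mask, each z plane's integrated density is multiplied by its
#' plane index and the sum is divided by the total integrated density --
#' the centre of mass along z in z-step units (1-based).
#'
#' @param z_stack 3D array (x, y, z).
#' @param mask 2D logical mask over (x, y).
#' @return z position in step units.
#' @export
z_centroid <- function(z_stack, mask) {
  nz <- dim(z_stack)[3]
  if (is.na(nz) || nz < 2) stop("z_stack needs at least 2 planes")
  dens <- vapply(seq_len(nz), function(k) sum(z_stack[, , k][mask]), 0)
  tot <- sum(dens)
  if (tot <= 0) stop("undefined z centroid: zero integrated density")
  sum(seq_len(nz) * dens) / tot
}

#' Count intensity foci by topographic prominence
#'
#' Counts local intensity maxima inside the mask whose topographic
#' prominence exceeds `prominence`, using 8-connectivity. Peaks are found
#' by a persistence sweep: pixels are processed in decreasing intensity,
#' components merge at their saddles, and the lower peak of a merging pair
#' dies with prominence equal to its height minus the saddle level; plateau
#' maxima count once.
#'
#' @param frame intensity matrix.
#' @param nucleus_mask logical mask restricting the search.
#' @param prominence prominence threshold (default 100, suitable for
#'   camera offsets on 8/16-bit acquisitions).
#' @return Number of foci.
#' @export
count_foci <- function(frame, nucleus_mask, prominence = 100) {
  if (prominence <= 0) stop("prominence must be positive")
  idx <- which(nucleus_mask)
  if (!length(idx)) return(0L)
  nr <- nrow(frame)
  vals <- frame[idx]
  ord <- idx[order(vals, decreasing = TRUE)]
  inmask_pos <- integer(length(frame)) # 0 = not yet added
  parent <- integer(0)
  peak_h <- numeric(0)
  prom <- numeric(0) # prominence at death; NA while alive
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  comp_of_pixel <- integer(length(frame))
  for (p in ord) {
    h <- frame[p]
    r <- (p - 1) %% nr + 1
    c <- (p - 1) %/% nr + 1
    neigh <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(frame)) next
      q <- (cc - 1) * nr + rr
      if (inmask_pos[q]) neigh <- c(neigh, q)
    }
    comps <- unique(vapply(neigh, function(q) find(comp_of_pixel[q]), 0L))
    if (!length(comps)) {
      parent <- c(parent, length(parent) + 1L)
      peak_h <- c(peak_h, h)
      prom <- c(prom, NA_real_)
      comp_of_pixel[p] <- length(parent)
    } else {
      winner <- comps[which.max(peak_h[comps])]
      for (cmp in comps) {
        if (cmp == winner) next
        prom[cmp] <- peak_h[cmp] - h # dies at this saddle level
        parent[cmp] <- winner
      }
      comp_of_pixel[p] <- winner
    }
    inmask_pos[p] <- 1L
  }
  floor_level <- min(vals)
  alive <- which(parent == seq_along(parent) & is.na(prom))
  prom[alive] <- peak_h[alive] - floor_level
  sum(prom > prominence)
}

#' Cumulative NEBD percentage
#'
#' The percentage of the cells counted on the first frame that have
#' undergone NEBD at or before each query frame.
#'
#' @param events per-cell NEBD frame indices (`NA` = no event).
#' @param n_initial number of nuclei counted on the first frame.
#' @param grid query frame indices.
#' @return Numeric vector of percentages along `grid`.
#' @export
cumulative_nebd <- function(events, n_initial, grid) {
  if (n_initial < sum(!is.na(events)))
    stop("n_initial smaller than the number of event-bearing cells")
  ev <- events[!is.na(events)]
  vapply(grid, function(g) 100 * sum(ev <= g) / n_initial, 0)
}
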
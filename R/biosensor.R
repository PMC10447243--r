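#' Background subtraction from non-ROI voxels
#'
#' The per-channel background is estimated as the median intensity over
#' voxels outside every ROI (mask == 0) — a robust choice when stray
#' foreground contaminates the non-axonal area — and subtracted from every
#' voxel, clipping at zero.
#'
#' @param stack a \linkS4class{BiosensorStack} whose mask contains
#'   background voxels.
#' @return list with \code{stack} (background-corrected) and
#'   \code{background} (named numeric per channel).
#' @export
subtractBackground <- function(stack) {
  stopifnot(is(stack, "BiosensorStack"))
  bgvox <- stack@mask == 0L
  if (!any(bgvox)) stop("mask contains no background voxels")
  nch <- dim(stack@img)[1]
  bg <- numeric(nch)
  img <- stack@img
  for (c in seq_len(nch)) {
    ch <- img[c, , , ]
    bg[c] <- median(ch[bgvox])
    img[c, , , ] <- pmax(0, ch - bg[c])
  }
  names(bg) <- stack@channelNames
  out <- stack
  out@img <- img
  list(stack = out, background = bg)
}

#' Per-axon ratiometric quantification over three regions
#'
#' The axon's voxels are partitioned into \code{n_regions} equal-length
#' intervals along the axon's principal spatial axis. Within each region the
#' pixel-wise numerator/denominator ratio is averaged
#' (\code{method = "pixel"}, the default) or the ratio of region mean
#' intensities is taken (\code{method = "pooled"}); the axon's raw ratio is
#' the mean over regions. A region whose denominator mean is not positive
#' invalidates the axon.
#'
#' @param stack a background-corrected \linkS4class{BiosensorStack}.
#' @param axon_id ROI label of the axon.
#' @param n_regions regions per axon (default 3).
#' @param num,den numerator and denominator channel indices (the ratio
#'   orientation is fixed per sensor; e.g. 950-nm over 840-nm excitation for
#'   an ATP/ADP sensor).
#' @param method per-region convention, \code{"pixel"} or \code{"pooled"}.
#' @return list: \code{ratio_raw} (NA when invalid), \code{region_means},
#'   \code{valid}, \code{note}.
#' @export
axonRatio <- function(stack, axon_id, n_regions = 3, num = 1, den = 2,
                      method = c("pixel", "pooled")) {
  stopifnot(is(stack, "BiosensorStack"))
  method <- match.arg(method)
  vox <- which(stack@mask == axon_id, arr.ind = TRUE)
  if (nrow(vox) < n_regions)
    stop("axon ", axon_id, " has fewer voxels than regions")
  # principal axis of the voxel cloud; project and cut into equal-length bins
  ctr <- scale(vox, scale = FALSE)
  axis1 <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  # fix the arbitrary SVD sign so region order is reproducible (region 1 at
  # the low-coordinate end of the dominant axis)
  if (axis1[which.max(abs(axis1))] < 0) axis1 <- -axis1
  proj <- drop(ctr %*% axis1)
  brk <- seq(min(proj), max(proj), length.out = n_regions + 1)
  bin <- findInterval(proj, brk, rightmost.closed = TRUE, all.inside = TRUE)
  va <- stack@img[cbind(num, vox)]
  vb <- stack@img[cbind(den, vox)]
  region_means <- rep(NA_real_, n_regions)
  for (r in seq_len(n_regions)) {
    ra <- va[bin == r]; rb <- vb[bin == r]
    if (!length(rb) || mean(rb) <= 0)
      return(list(ratio_raw = NA_real_, region_means = region_means,
                  valid = FALSE,
                  note = sprintf("axon %d region %d: denominator mean <= 0",
                                 axon_id, r)))
    region_means[r] <- if (method == "pixel") {
      keep <- rb > 0
      mean(ra[keep] / rb[keep])
    } else mean(ra) / mean(rb)
  }
  list(ratio_raw = mean(region_means), region_means = region_means,
       valid = TRUE, note = "")
}

#' Quantify every axon in a stack
#'
#' Convenience wrapper: background subtraction, per-axon three-region
#' ratios, and normalization of the ratio column to a control mean when
#' control values are supplied.
#'
#' @inheritParams axonRatio
#' @param stack a raw \linkS4class{BiosensorStack}.
#' @param stages optional named/ordered integer FAD stage per axon id
#'   (staging is an input annotation, not computed).
#' @return data.frame: axon_id, stage, ratio_raw, valid, note.
#' @export
quantifyAxons <- function(stack, n_regions = 3, num = 1, den = 2,
                          method = "pixel", stages = NULL) {
  corr <- subtractBackground(stack)$stack
  ids <- roiIds(corr)
  rows <- lapply(ids, function(k) {
    r <- axonRatio(corr, k, n_regions, num, den, method)
    data.frame(axon_id = k,
               stage = if (is.null(stages)) NA_integer_ else stages[k],
               ratio_raw = r$ratio_raw, valid = r$valid, note = r$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize measurements to the control-group mean
#'
#' Divides every value by the mean of the control values, eliminating batch
#' differences; the control group normalizes to mean 1.
#'
#' @param values numeric vector to normalize.
#' @param control control-group values (nonempty, positive mean).
#' @return normalized values.
#' @export
normalizeToControl <- function(values, control) {
  if (!length(control)) stop("control set is empty")
  m <- mean(control, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("control mean must be > 0")
  values / m
}

#' Crosstalk-corrected FRET signal
#'
#' cFRET = acceptor - alpha * donor, with the crosstalk fraction alpha
#' measured on donor-only specimens; the reported sensor readout is the
#' cFRET:donor ratio. Records with non-positive donor or negative cFRET are
#' flagged invalid.
#'
#' @param donor,acceptor background-corrected channel intensities
#'   (vectorized).
#' @param alpha crosstalk fraction in [0, 1).
#' @return data.frame: cfret, ratio, valid.
#' @export
cfret <- function(donor, acceptor, alpha) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  cf <- acceptor - alpha * donor
  valid <- donor > 0 & cf >= 0
  ratio <- ifelse(donor > 0, cf / donor, NA_real_)
  data.frame(cfret = cf, ratio = ratio, valid = valid)
}

#' Per-stage fraction above the control mean + k s.d.
#'
#' The classification threshold is the control mean plus \code{k} sample
#' standard deviations (n-1 denominator, appropriate for small control
#' groups); reported is the fraction of values strictly above it, per stage.
#'
#' @param values measurement per organelle/axon.
#' @param stage FAD stage per value.
#' @param control control-group values (>= 2).
#' @param k s.d. multiplier (default 3).
#' @return list: \code{threshold}, \code{fraction} (named by stage).
#' @export
outlierFraction <- function(values, stage, control, k = 3) {
  if (length(control) < 2) stop("need >= 2 control values")
  thr <- mean(control) + k * sd(control)
  fr <- tapply(values > thr, stage, mean)
  list(threshold = thr, fraction = fr)
}

#' Paired gradient analysis (near vs far measurements)
#'
#' Two-sided paired t-test on (near - far) for axons measured both far from
#' and close to a lesion. Axons lacking either tag are dropped with a note.
#' When all differences are identical the t-test degenerates: a zero mean
#' difference reports p = 1, a nonzero constant difference reports p = 0
#' with a zero-variance flag.
#'
#' @param axon_id,location,value vectors: per measurement, the axon id, its
#'   location tag (\code{"far"}/\code{"near"}) and the measured value.
#' @return list: n_pairs, mean_diff, t, p, zero_variance, dropped.
#' @export
pairedGradient <- function(axon_id, location, value) {
  stopifnot(all(location %in% c("far", "near")))
  far <- tapply(value[location == "far"], axon_id[location == "far"], mean)
  near <- tapply(value[location == "near"], axon_id[location == "near"], mean)
  ids <- intersect(names(far), names(near))
  dropped <- setdiff(union(names(far), names(near)), ids)
  if (length(ids) < 2) stop("need >= 2 paired axons")
  d <- near[ids] - far[ids]
  if (sd(d) <= 1e-12 * max(abs(d), 1)) {
    md <- mean(d)
    return(list(n_pairs = length(ids), mean_diff = md,
                t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                zero_variance = TRUE, dropped = dropped))
  }
  tt <- t.test(near[ids], far[ids], paired = TRUE)
  list(n_pairs = length(ids), mean_diff = unname(tt$estimate),
       t = unname(tt$statistic), p = tt$p.value,
       zero_variance = FALSE, dropped = dropped)
}

#' Marker puncta quantification within a reference mask
#'
#' Mitochondrial-marker puncta are detected inside a reference structure
#' (e.g. neurofilament-positive axons): pixels exceeding
#' \code{intensity_cutoff_factor} times the mean reference intensity are
#' kept, connected components smaller than \code{min_size_px} pixels are
#' discarded. Occupancy is the puncta area over the reference area, MFI the
#' mean intensity over puncta pixels, and integrated density their product.
#'
#' @param image 2-d numeric intensity matrix.
#' @param ref_mask logical matrix of the reference structure (nonempty).
#' @param intensity_cutoff_factor detection threshold as a multiple of the
#'   mean reference intensity (default 1.2, i.e. a 120% cutoff).
#' @param min_size_px minimum punctum size in pixels (default 4).
#' @return list: occupancy, mfi, integrated_density, n_puncta, no_puncta
#'   flag.
#' @export
markerQuantification <- function(image, ref_mask,
                                 intensity_cutoff_factor = 1.2,
                                 min_size_px = 4) {
  stopifnot(is.matrix(image), identical(dim(image), dim(ref_mask)))
  ref_mask <- ref_mask > 0
  if (!any(ref_mask)) stop("reference mask is empty")
  thr <- intensity_cutoff_factor * mean(image[ref_mask])
  cand <- (image > thr) & ref_mask
  if (!any(cand))
    return(list(occupancy = 0, mfi = 0, integrated_density = 0,
                n_puncta = 0L, no_puncta = TRUE))
  lab <- EBImage::bwlabel(cand)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_px)
  if (!length(keep))
    return(list(occupancy = 0, mfi = 0, integrated_density = 0,
                n_puncta = 0L, no_puncta = TRUE))
  puncta <- lab %in% keep & lab > 0
  occ <- sum(puncta) / sum(ref_mask)
  mfi <- mean(image[puncta])
  list(occupancy = occ, mfi = mfi, integrated_density = occ * mfi,
       n_puncta = length(keep), no_puncta = FALSE)
}

#' Cytochrome c oxidase occupancy of an axon
#'
#' Percentage of the axonal area occupied by COX-active elements.
#'
#' @param axon_mask logical matrix/array of the axon (nonempty).
#' @param cox_map logical matrix/array of COX-positive pixels, same shape.
#' @param min_length_um minimum axon length for inclusion (default 25 µm);
#'   checked only when \code{axon_length_um} is supplied.
#' @param axon_length_um measured axon length in µm, if known.
#' @return occupancy percentage in [0, 100].
#' @export
coxOccupancy <- function(axon_mask, cox_map, min_length_um = 25,
                         axon_length_um = NULL) {
  axon_mask <- axon_mask > 0
  if (!any(axon_mask)) stop("axon mask is empty")
  stopifnot(identical(dim(axon_mask), dim(cox_map)))
  if (!is.null(axon_length_um) && axon_length_um < min_length_um)
    stop("axon shorter than the ", min_length_um, " um inclusion minimum")
  100 * sum(cox_map > 0 & axon_mask) / sum(axon_mask)
}

#' Mitochondrial shape factor
#'
#' Length divided by width of a single mitochondrion; 1 is round.
#'
#' @param length_um,width_um organelle dimensions (vectorized); width must
#'   be positive, invalid records return NA.
#' @return numeric shape factors.
#' @export
shapeFactor <- function(length_um, width_um) {
  ifelse(width_um > 0, length_um / width_um, NA_real_)
}
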
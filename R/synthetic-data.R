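#' Design of a synthetic LFQ proteomics experiment
#'
#' Captures the statistical structure the downstream analysis assumes:
#' log-normal LFQ intensities with protein-specific locations, planted
#' case-vs-control log2 fold changes on chosen proteins, technical-replicate
#' pairs that differ only by noise, and intensity-dependent (left-censored)
#' missingness controlled by a per-sample quantile threshold.
#'
#' @param n_control,n_case biological samples per group (each >= 2).
#' @param n_tech_reps technical replicates per biological sample.
#' @param n_proteins number of proteins in the universe.
#' @param pathways named list of protein-id vectors (subsets of the universe).
#' @param effect_log2fc named numeric of planted log2 fold changes
#'   (case - control); unnamed proteins have effect 0.
#' @param base_mean_log2,base_sd_log2 location/scale of the protein-specific
#'   log2-intensity baseline. Defaults 25 and 2 reflect typical MaxQuant LFQ
#'   log2 intensities.
#' @param bio_sd,tech_sd biological and technical log2-scale noise s.d.
#' @param censor_quantile fraction in [0, 1): per-sample intensity quantile
#'   below which values tend to go missing.
#' @param censor_jitter logistic scale (log2 units) of the soft censoring
#'   threshold; 0 gives a hard cut.
#' @param seed integer seed; generation is bit-reproducible.
#' @return a list of class \code{"SimDesign"}.
#' @export
simDesign <- function(n_control = 6, n_case = 5, n_tech_reps = 2,
                      n_proteins = 2000, pathways = list(),
                      effect_log2fc = numeric(),
                      base_mean_log2 = 25, base_sd_log2 = 2,
                      bio_sd = 0.3, tech_sd = 0.1,
                      censor_quantile = 0, censor_jitter = 0.3,
                      seed = 1L) {
  if (n_proteins < 1) stop("design is degenerate: n_proteins must be >= 1")
  if (n_control < 2 || n_case < 2)
    stop("n_control and n_case must each be >= 2")
  if (n_tech_reps < 1) stop("n_tech_reps must be >= 1")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("censor_quantile must lie in [0, 1)")
  universe <- sprintf("P%04d", seq_len(n_proteins))
  for (pw in names(pathways)) {
    if (!all(pathways[[pw]] %in% universe))
      stop("pathway '", pw, "' contains proteins outside the universe")
  }
  if (length(effect_log2fc) && !all(names(effect_log2fc) %in% universe))
    stop("effect_log2fc names outside the protein universe")
  structure(list(
    n_control = n_control, n_case = n_case, n_tech_reps = n_tech_reps,
    n_proteins = n_proteins, universe = universe, pathways = pathways,
    effect_log2fc = effect_log2fc, base_mean_log2 = base_mean_log2,
    base_sd_log2 = base_sd_log2, bio_sd = bio_sd, tech_sd = tech_sd,
    censor_quantile = censor_quantile, censor_jitter = censor_jitter,
    seed = as.integer(seed)), class = "SimDesign")
}

#' Simulate an LFQ proteomics dataset
#'
#' Draws protein-specific log2 locations from the baseline distribution,
#' adds group shifts for proteins with planted effects, biological noise per
#' biological sample and technical noise per replicate run, then censors:
#' each run's values below its \code{censor_quantile} intensity threshold go
#' missing with probability given by a logistic ramp around the threshold,
#' so missingness is intensity-dependent (MNAR) by construction.
#'
#' @param design a \code{\link{simDesign}}.
#' @return list with \code{lfq} (an \linkS4class{LfqExperiment}, log2 scale,
#'   one column per technical replicate run), \code{annotation} (per-protein
#'   annotation data.frame: mitochondrial membership, sub-mitochondrial
#'   location, pathway membership, genome of origin, half-life), and
#'   \code{truth} (per-protein planted log2fc and the complete pre-censoring
#'   matrix).
#' @examples
#' d <- simDesign(n_proteins = 50, seed = 7)
#' sim <- simulateLfq(d)
#' sim$lfq
#' @export
simulateLfq <- function(design) {
  stopifnot(inherits(design, "SimDesign"))
  set.seed(design$seed)
  ids <- design$universe
  n_bio <- design$n_control + design$n_case
  groups_bio <- rep(c("control", "case"), c(design$n_control, design$n_case))
  bio_ids <- sprintf("%s_%d", groups_bio,
                     c(seq_len(design$n_control), seq_len(design$n_case)))
  effect <- setNames(numeric(length(ids)), ids)
  effect[names(design$effect_log2fc)] <- design$effect_log2fc

  mu <- rnorm(length(ids), design$base_mean_log2, design$base_sd_log2)
  bio <- mu + outer(effect, as.numeric(groups_bio == "case")) +
    matrix(rnorm(length(ids) * n_bio, 0, design$bio_sd), length(ids), n_bio)

  runs <- bio[, rep(seq_len(n_bio), each = design$n_tech_reps), drop = FALSE] +
    matrix(rnorm(length(ids) * n_bio * design$n_tech_reps, 0, design$tech_sd),
           length(ids), n_bio * design$n_tech_reps)
  run_bio <- rep(bio_ids, each = design$n_tech_reps)
  run_grp <- rep(groups_bio, each = design$n_tech_reps)
  colnames(runs) <- sprintf("%s_r%d", run_bio,
                            rep(seq_len(design$n_tech_reps), n_bio))
  rownames(runs) <- ids
  complete <- runs

  if (design$censor_quantile > 0) {
    for (j in seq_len(ncol(runs))) {
      thr <- quantile(runs[, j], design$censor_quantile, names = FALSE)
      p_miss <- if (design$censor_jitter > 0)
        plogis((thr - runs[, j]) / design$censor_jitter)
      else as.numeric(runs[, j] < thr)
      runs[runif(nrow(runs)) < p_miss, j] <- NA
    }
  }

  annotation <- .annotateUniverse(ids, design$pathways)
  truth <- data.frame(protein_id = ids, log2fc_true = unname(effect),
                      base_log2 = mu, stringsAsFactors = FALSE)
  lfq <- LfqExperiment(runs, group = run_grp, biosample = run_bio,
                       scale = "log2")
  list(lfq = lfq, annotation = annotation, truth = truth, complete = complete)
}

# Pathway members are flagged mitochondrial; the rest are split between a
# mitochondrial background and non-mito contaminants, with plausible
# sub-mitochondrial locations, genome of origin and half-lives.
.annotateUniverse <- function(ids, pathways) {
  pw_string <- vapply(ids, function(id) {
    hits <- names(pathways)[vapply(pathways, function(p) id %in% p, logical(1))]
    paste(hits, collapse = ";")
  }, character(1))
  in_pw <- nzchar(pw_string)
  is_mito <- in_pw | (seq_along(ids) %% 3 != 0)
  loc <- rep("unknown", length(ids))
  loc[is_mito] <- c("matrix", "IMM", "OMM", "IMS")[
    1 + (seq_len(sum(is_mito)) %% 4)]
  genome <- ifelse(is_mito & (seq_along(ids) %% 40 == 0), "mtDNA", "nuclear")
  half_life <- round(rlnorm(length(ids), log(10), 0.5), 2)
  data.frame(protein_id = ids, is_mito = is_mito,
             submito_location = loc, pathways = pw_string,
             genome = genome, half_life = half_life,
             stringsAsFactors = FALSE)
}

#' Design of a synthetic two-channel biosensor imaging experiment
#'
#' @param n_axons axons to paint into the volume.
#' @param stage_probs probabilities of focal axonal degeneration (FAD)
#'   stages 0 (normal), 1 (swollen), 2 (fragmented); must sum to 1.
#' @param true_ratio_by_stage true sensor ratio per stage (numerator over
#'   denominator channel), all > 0.
#' @param background_per_channel additive background per channel.
#' @param crosstalk_alpha fraction of the donor signal bleeding into the
#'   acceptor channel (FRET mode); 0 disables crosstalk.
#' @param noise_sd Gaussian read-noise s.d. added to every voxel.
#' @param stack_shape integer (z, y, x) volume shape.
#' @param axon_width axon tube width in voxels.
#' @param signal_level denominator-channel signal amplitude inside axons.
#' @param seed integer seed.
#' @return a list of class \code{"SimImagingDesign"}.
#' @export
simImagingDesign <- function(n_axons = 12, stage_probs = c(0.6, 0.25, 0.15),
                             true_ratio_by_stage = c(1.0, 0.8, 0.6),
                             background_per_channel = c(50, 20),
                             crosstalk_alpha = 0, noise_sd = 2,
                             stack_shape = c(4, 64, 64), axon_width = 3,
                             signal_level = 100, seed = 1L) {
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("stage_probs must sum to 1")
  if (any(true_ratio_by_stage <= 0)) stop("true ratios must be > 0")
  if (crosstalk_alpha < 0 || crosstalk_alpha >= 1)
    stop("crosstalk_alpha must lie in [0, 1)")
  structure(list(n_axons = n_axons, stage_probs = stage_probs,
                 true_ratio_by_stage = true_ratio_by_stage,
                 background_per_channel = background_per_channel,
                 crosstalk_alpha = crosstalk_alpha, noise_sd = noise_sd,
                 stack_shape = as.integer(stack_shape),
                 axon_width = as.integer(axon_width),
                 signal_level = signal_level, seed = as.integer(seed)),
            class = "SimImagingDesign")
}

#' Simulate a two-channel biosensor image stack with ground truth
#'
#' Axons are straight tubes along x, each confined to one z-plane, painted
#' into the label mask. The denominator channel carries the signal plus its
#' background; the numerator (acceptor) channel is
#' \code{true_ratio * signal + crosstalk_alpha * donor_signal + background}.
#' Gaussian read noise is added everywhere. Tube geometry is deliberately
#' simple: the ratio arithmetic, not morphology, is what downstream code
#' consumes.
#'
#' @param design a \code{\link{simImagingDesign}}.
#' @return list with \code{stack} (a \linkS4class{BiosensorStack}; channel 1
#'   is the numerator/acceptor, channel 2 the denominator/donor) and
#'   \code{truth} (data.frame of axon id, FAD stage, true ratio).
#' @export
simulateBiosensorStack <- function(design) {
  stopifnot(inherits(design, "SimImagingDesign"))
  set.seed(design$seed)
  shp <- design$stack_shape
  z <- shp[1]; ny <- shp[2]; nx <- shp[3]
  w <- design$axon_width
  lanes_per_plane <- ny %/% (2 * w)   # one-tube gap between lanes
  capacity <- lanes_per_plane * z
  if (design$n_axons > capacity)
    stop("stack too small: ", design$n_axons, " axons need > ", capacity,
         " lanes of width ", w, " with spacing in a ",
         paste(shp, collapse = "x"), " volume")

  mask <- array(0L, dim = shp)
  stages <- sample(0:2, design$n_axons, replace = TRUE,
                   prob = design$stage_probs)
  slots <- sample(capacity, design$n_axons)
  for (k in seq_len(design$n_axons)) {
    zi <- (slots[k] - 1) %/% lanes_per_plane + 1
    lane <- (slots[k] - 1) %% lanes_per_plane
    y0 <- lane * 2 * w + 1
    mask[zi, y0:(y0 + w - 1), ] <- k
  }

  sig <- design$signal_level
  bgA <- design$background_per_channel[1]
  bgB <- design$background_per_channel[2]
  ratio <- design$true_ratio_by_stage[stages + 1]

  den_sig <- array(0, dim = shp)
  num_sig <- array(0, dim = shp)
  for (k in seq_len(design$n_axons)) {
    vox <- mask == k
    den_sig[vox] <- sig
    num_sig[vox] <- ratio[k] * sig + design$crosstalk_alpha * sig
  }
  noise <- function() if (design$noise_sd > 0)
    array(rnorm(prod(shp), 0, design$noise_sd), shp) else 0
  chA <- pmax(0, num_sig + bgA + noise())
  chB <- pmax(0, den_sig + bgB + noise())

  img <- array(0, dim = c(2, shp))
  img[1, , , ] <- chA
  img[2, , , ] <- chB
  stack <- BiosensorStack(img, mask, channelNames = c("numerator", "denominator"))
  truth <- data.frame(axon_id = seq_len(design$n_axons), stage = stages,
                      true_ratio = ratio)
  list(stack = stack, truth = truth)
}

#' Simulate a single-organelle measurement table
#'
#' Per-organelle morphology (length, width, shape factor = length/width) and
#' two channel intensities whose ratio is drawn per FAD stage, emulating
#' single-mitochondrion ratiometric scatter data.
#'
#' @param n_per_stage integer length-3: organelles per FAD stage 0, 1, 2.
#' @param ratio_mean,ratio_sd length-3 stage-wise ratio mean and s.d.
#' @param shape_mean,shape_sd length-3 stage-wise shape-factor mean and s.d.
#'   (truncated below at 1: a mitochondrion is at least as long as wide).
#' @param width_um mean organelle width in micrometres.
#' @param intensity denominator channel mean intensity.
#' @param seed integer seed.
#' @return data.frame: organelle id, axon id, stage, channel intensities,
#'   length, width, shape_factor, ratio.
#' @export
simulateOrganelleTable <- function(n_per_stage = c(200, 100, 60),
                                   ratio_mean = c(1, 1, 1.5),
                                   ratio_sd = c(0.1, 0.1, 0.2),
                                   shape_mean = c(3, 2, 1.3),
                                   shape_sd = c(0.6, 0.5, 0.2),
                                   width_um = 0.4, intensity = 100,
                                   seed = 1L) {
  if (any(ratio_mean <= 0) || any(ratio_sd < 0) || any(shape_sd < 0))
    stop("stage parameters must be positive")
  set.seed(as.integer(seed))
  stage <- rep(0:2, n_per_stage)
  n <- length(stage)
  ratio <- rnorm(n, ratio_mean[stage + 1], ratio_sd[stage + 1])
  ratio <- pmax(ratio, 1e-6)
  sf <- pmax(1, rnorm(n, shape_mean[stage + 1], shape_sd[stage + 1]))
  width <- pmax(0.05, rnorm(n, width_um, width_um / 10))
  den <- rnorm(n, intensity, intensity / 20)
  data.frame(organelle_id = seq_len(n),
             axon_id = ((seq_len(n) - 1) %/% 5) + 1,
             stage = stage,
             intensity_num = ratio * den, intensity_den = den,
             length_um = sf * width, width_um = width,
             shape_factor = sf, ratio = ratio)
}

#' Simulate a relative enzyme-abundance profile
#'
#' Per-enzyme scale factors E(sample)/E(mean control): the dimensionless
#' multipliers the kinetic model applies to its maximal rates. Optional
#' log-normal noise is centred so the geometric mean equals the configured
#' factor.
#'
#' @param factors named numeric of relative abundances (> 0), e.g.
#'   \code{c(Idh3a = 0.5, Ndufs1 = 0.7)}.
#' @param noise_sd s.d. of log-normal multiplicative noise (natural log); 0
#'   for exact factors.
#' @param seed integer seed.
#' @return named numeric vector of class \code{"EnzymeAbundanceProfile"}.
#' @export
simulateAbundanceProfile <- function(factors, noise_sd = 0, seed = 1L) {
  if (any(factors <= 0)) stop("abundance factors must be > 0")
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("factors must be a named vector of enzyme ids")
  set.seed(as.integer(seed))
  out <- factors * exp(rnorm(length(factors), 0, noise_sd))
  structure(out, class = "EnzymeAbundanceProfile")
}
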
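#' Average technical replicates of an LfqExperiment
#'
#' Collapses technical-replicate runs to one column per biological sample.
#' Each cell is the mean of the non-missing replicate values; a cell with no
#' observed replicate stays missing.
#'
#' @param x an \linkS4class{LfqExperiment} whose \code{colData$biosample}
#'   maps runs to biological samples.
#' @return an LfqExperiment with one column per biological sample.
#' @export
averageTechnicalReplicates <- function(x) {
  stopifnot(is(x, "LfqExperiment"))
  cd <- SummarizedExperiment::colData(x)
  bios <- unique(cd$biosample)
  a <- lfqAssay(x)
  out <- matrix(NA_real_, nrow(a), length(bios),
                dimnames = list(rownames(a), bios))
  grp <- character(length(bios))
  for (i in seq_along(bios)) {
    cols <- which(cd$biosample == bios[i])
    g <- unique(cd$group[cols])
    if (length(g) != 1)
      stop("replicates of biosample '", bios[i],
           "' span different experimental groups")
    grp[i] <- g
    out[, i] <- rowMeans(a[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  LfqExperiment(out, group = grp, biosample = bios, scale = scaleFlag(x),
                rowData = SummarizedExperiment::rowData(x))
}

#' Two-tier imputation of missing LFQ values
#'
#' Tier 1 targets left-censored proteins: for any protein detected in fewer
#' than \code{detect_frac} of the samples within at least one experimental
#' group, all of that protein's values in that group are replaced by draws
#' from \code{Normal(mu_all - shift_sd * sd_all, (width_sd * sd_all)^2)},
#' where \code{mu_all} and \code{sd_all} are the mean and s.d. of all
#' observed log2 intensities in the dataset. By default observed values in
#' such a group are overwritten along with the missing ones;
#' \code{overwrite_observed = FALSE} restricts tier 1 to missing cells.
#'
#' Tier 2 imputes the remaining missing cells by chained equations: each
#' sample column with missing values is regressed on all other columns
#' (stochastic linear regression, residual noise added), sweeping all
#' columns per iteration for a fixed number of iterations.
#'
#' @param x an \linkS4class{LfqExperiment} on the log2 scale, >= 2 samples
#'   per group.
#' @param shift_sd downward shift of the tier-1 mean, in units of the global
#'   s.d. (default 2).
#' @param width_sd tier-1 s.d. as a fraction of the global s.d. (default
#'   0.3, controlling zero inflation).
#' @param detect_frac detection-fraction threshold triggering tier 1
#'   (default 0.5).
#' @param n_iter chained-equation sweeps (default 10).
#' @param overwrite_observed replace observed values of tier-1 groups too
#'   (default TRUE).
#' @param seed integer seed for both tiers.
#' @return list with \code{lfq} (no missing cells) and \code{tiers}, a
#'   character matrix over cells: \code{"none"}, \code{"shifted_gaussian"}
#'   or \code{"chained"}.
#' @export
imputeLfq <- function(x, shift_sd = 2, width_sd = 0.3, detect_frac = 0.5,
                      n_iter = 10, overwrite_observed = TRUE, seed = 1L) {
  stopifnot(is(x, "LfqExperiment"))
  if (scaleFlag(x) != "log2") stop("impute expects a log2-scale matrix")
  a <- lfqAssay(x)
  grp <- sampleGroups(x)
  if (any(table(grp) < 2)) stop("each group needs >= 2 samples")
  obs <- a[!is.na(a)]
  if (length(obs) < 2 || sd(obs) == 0)
    stop("degenerate dataset: overall s.d. of observed values is 0")
  mu_all <- mean(obs); sd_all <- sd(obs)
  set.seed(as.integer(seed))
  tiers <- matrix("none", nrow(a), ncol(a), dimnames = dimnames(a))

  for (g in unique(grp)) {
    cols <- which(grp == g)
    det <- rowMeans(!is.na(a[, cols, drop = FALSE]))
    hit <- which(det < detect_frac)
    for (i in hit) {
      cells <- if (overwrite_observed) cols else cols[is.na(a[i, cols])]
      if (!length(cells)) next
      a[i, cells] <- rnorm(length(cells), mu_all - shift_sd * sd_all,
                           width_sd * sd_all)
      tiers[i, cells] <- "shifted_gaussian"
    }
  }

  miss <- is.na(a)
  if (any(miss)) {
    tiers[miss] <- "chained"
    a <- .chainedImpute(a, n_iter)
  }
  out <- x
  SummarizedExperiment::assay(out, "lfq") <- a
  list(lfq = out, tiers = tiers)
}

# Chained-equation imputation: initialize missing cells at the row mean
# (protein-wise), then sweep sample columns, regressing each on all others
# over rows observed in that column and drawing predictions with residual
# noise. Assumes set.seed was called by the caller.
.chainedImpute <- function(a, n_iter) {
  miss <- is.na(a)
  row_mu <- rowMeans(a, na.rm = TRUE)
  row_mu[is.nan(row_mu)] <- mean(a, na.rm = TRUE)
  for (j in seq_len(ncol(a))) a[miss[, j], j] <- row_mu[miss[, j]]
  for (it in seq_len(n_iter)) {
    for (j in seq_len(ncol(a))) {
      mj <- miss[, j]
      if (!any(mj)) next
      fit <- lm.fit(cbind(1, a[!mj, -j, drop = FALSE]), a[!mj, j])
      res_sd <- sqrt(sum(fit$residuals^2) /
                       max(1, sum(!mj) - length(fit$coefficients)))
      pred <- drop(cbind(1, a[mj, -j, drop = FALSE]) %*% fit$coefficients)
      a[mj, j] <- pred + rnorm(sum(mj), 0, res_sd)
    }
  }
  a
}

#' PCA quality control over samples
#'
#' Principal-component analysis with samples as observations and proteins as
#' centered features. Samples are flagged as outliers when their distance
#' from the centroid in the PC1--PC2 plane exceeds the median distance plus
#' \code{k_mad} times the median absolute deviation of distances; removal is
#' left to the caller.
#'
#' @param x an imputed log2 \linkS4class{LfqExperiment} (>= 3 samples).
#' @param k_mad MAD multiplier of the outlier rule (default 3).
#' @return list with \code{coords} (sample x PC1/PC2), \code{explained}
#'   (variance fractions for all components), and \code{outliers} (logical
#'   per sample).
#' @export
pcaQc <- function(x, k_mad = 3) {
  stopifnot(is(x, "LfqExperiment"))
  a <- lfqAssay(x)
  if (anyNA(a)) stop("pcaQc expects an imputed (complete) matrix")
  if (ncol(a) < 3) stop("at least 3 samples are required")
  pc <- prcomp(t(a), center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, 1:2, drop = FALSE]
  d <- sqrt(rowSums(coords^2))
  out <- (d - median(d)) > k_mad * mad(d, constant = 1.4826)
  list(coords = coords, explained = explained,
       outliers = setNames(out, colnames(a)))
}

#' Differential protein abundance between case and control
#'
#' Per protein: two-sided equal-variance Student's t-test on log2
#' intensities, log2 fold change as mean(case) - mean(control), and
#' Bonferroni-adjusted p-values \code{p_bonf = min(1, m * p_raw)} over the m
#' tested proteins. The t statistics are computed vectorised from the pooled
#' formula.
#'
#' @param x an imputed log2 \linkS4class{LfqExperiment} with both groups
#'   present (>= 2 samples each).
#' @param tiers optional tier matrix from \code{\link{imputeLfq}}; when
#'   given, each protein's dominant imputation mechanism is reported.
#' @return data.frame: protein_id, log2fc, t_stat, p_raw, p_bonf,
#'   n_control_obs, n_case_obs, imputation_tier.
#' @export
differentialAbundance <- function(x, tiers = NULL) {
  stopifnot(is(x, "LfqExperiment"))
  a <- lfqAssay(x)
  if (anyNA(a)) stop("differentialAbundance expects an imputed matrix")
  grp <- sampleGroups(x)
  n1 <- sum(grp == "control"); n2 <- sum(grp == "case")
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  ctl <- a[, grp == "control", drop = FALSE]
  cas <- a[, grp == "case", drop = FALSE]
  m1 <- rowMeans(ctl); m2 <- rowMeans(cas)
  v1 <- apply(ctl, 1, var); v2 <- apply(cas, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  tt[se == 0 & m1 == m2] <- 0
  p <- 2 * pt(abs(tt), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & m1 == m2] <- 1
  tier_of <- rep("none", nrow(a))
  if (!is.null(tiers)) {
    tier_of <- apply(tiers, 1, function(r) {
      if (any(r == "shifted_gaussian")) "shifted_gaussian"
      else if (any(r == "chained")) "chained" else "none"
    })
  }
  data.frame(protein_id = rownames(a), log2fc = m2 - m1, t_stat = tt,
             p_raw = p, p_bonf = pmin(1, p * nrow(a)),
             n_control_obs = n1, n_case_obs = n2,
             imputation_tier = tier_of, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Complex-level one-way ANOVA
#'
#' For each protein complex, the per-sample mean log2 LFQ of its member
#' proteins is compared across experimental groups by one-way ANOVA.
#'
#' @param x an imputed log2 \linkS4class{LfqExperiment}.
#' @param membership named list: complex id -> protein id vector.
#' @return data.frame: complex, n_proteins, F, p. Empty complexes are
#'   skipped with a warning.
#' @export
complexLevelAnova <- function(x, membership) {
  stopifnot(is(x, "LfqExperiment"), is.list(membership))
  a <- lfqAssay(x)
  grp <- factor(sampleGroups(x))
  if (nlevels(grp) < 2) stop("at least two experimental groups are required")
  res <- lapply(names(membership), function(cx) {
    rows <- intersect(membership[[cx]], rownames(a))
    if (!length(rows)) {
      warning("complex '", cx, "' has no measured proteins; skipped")
      return(NULL)
    }
    y <- colMeans(a[rows, , drop = FALSE])
    av <- anova(lm(y ~ grp))
    data.frame(complex = cx, n_proteins = length(rows),
               F = av[["F value"]][1], p = av[["Pr(>F)"]][1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank proteins by log2 fold change
#'
#' Proteins sorted ascending by log2fc (most depleted first), ties broken by
#' protein id (lexicographic) for determinism, with a membership flag column
#' per requested pathway.
#'
#' @param d a differential table from \code{\link{differentialAbundance}}.
#' @param annotation per-protein annotation with a semicolon-separated
#'   \code{pathways} column (as produced by \code{\link{simulateLfq}}).
#' @param pathway_ids pathways to flag.
#' @return the differential table rows with \code{rank} and one logical
#'   \code{in_<pathway>} column per pathway.
#' @export
rankByLog2fc <- function(d, annotation, pathway_ids = character()) {
  ord <- order(d$log2fc, d$protein_id)
  out <- d[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  pw <- strsplit(annotation$pathways[match(out$protein_id,
                                           annotation$protein_id)], ";")
  for (id in pathway_ids)
    out[[paste0("in_", id)]] <- vapply(pw, function(p) id %in% p, logical(1))
  rownames(out) <- NULL
  out
}

#' Correlate differential results with an external per-protein value
#'
#' Pearson (default) or Spearman correlation between log2 fold changes and
#' an external quantity (e.g. transcript log2fc, protein half-life) over the
#' intersecting proteins.
#'
#' @param d a differential table.
#' @param external named numeric: protein id -> value.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
correlateExternal <- function(d, external, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(d$protein_id, names(external))
  if (length(common) < 3)
    stop("need >= 3 overlapping proteins, got ", length(common))
  a <- d$log2fc[match(common, d$protein_id)]
  b <- external[common]
  ct <- cor.test(a, b, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
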
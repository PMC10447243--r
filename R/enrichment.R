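#' Weighted running-sum enrichment score
#'
#' Classic gene set enrichment statistic: walking down a list ranked by
#' descending score, the running sum gains \code{|score|^p} (normalised over
#' the in-set total) at set members and loses \code{1/(N - n)} at
#' non-members; the enrichment score (ES) is the signed maximum deviation
#' from zero. With \code{p = 0} every hit contributes equally and the
#' statistic reduces to a Kolmogorov--Smirnov walk.
#'
#' @param scores named numeric vector of ranking scores (names are gene/
#'   protein ids); sorted internally by descending score, ties broken by id.
#' @param gene_set character vector of set member ids; must intersect the
#'   list.
#' @param p hit-weighting exponent (default 1).
#' @return list with \code{es} and \code{running} (the running-sum profile
#'   over list positions).
#' @export
enrichmentScore <- function(scores, gene_set, p = 1) {
  if (anyDuplicated(names(scores))) stop("duplicate ids in the ranked list")
  if (any(!is.finite(scores))) stop("scores must be finite")
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  inset <- names(s) %in% gene_set
  n_hit <- sum(inset)
  N <- length(s)
  if (n_hit == 0) stop("gene set does not intersect the ranked list")
  if (n_hit == N)   # hits and misses degenerate; define ES = 0
    return(list(es = 0, running = rep(0, N)))
  w <- abs(s)^p
  hit_inc <- numeric(N)
  denom <- sum(w[inset])
  hit_inc[inset] <- if (denom > 0) w[inset] / denom else 1 / n_hit
  miss_dec <- numeric(N)
  miss_dec[!inset] <- 1 / (N - n_hit)
  running <- cumsum(hit_inc - miss_dec)
  # ties in |running| (possible with discretised scores) break to the
  # earliest position, within float tolerance
  mx <- max(abs(running))
  es <- running[which(abs(running) >= mx - 1e-12)[1]]
  list(es = es, running = running)
}

#' Permutation-calibrated normalized enrichment score
#'
#' The null distribution is built by gene-label permutation: \code{n_perm}
#' random sets of the same size drawn from the ranked list. NES is the ES
#' divided by the mean |null ES| of matching sign, and the permutation p is
#' \code{(1 + #same-sign nulls at least as extreme) / (1 + #same-sign
#' nulls)}, so p is never zero.
#'
#' @param scores named numeric ranking scores.
#' @param gene_set set member ids.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param p hit-weighting exponent passed to \code{\link{enrichmentScore}}.
#' @param seed integer seed.
#' @return list: \code{es}, \code{nes}, \code{p_perm}, \code{set_size},
#'   \code{n_perm}.
#' @export
permutationNes <- function(scores, gene_set, n_perm = 1000, p = 1, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  es <- enrichmentScore(scores, gene_set, p = p)$es
  size <- sum(names(scores) %in% gene_set)
  set.seed(as.integer(seed))
  ids <- names(scores)
  null_es <- vapply(seq_len(n_perm), function(i)
    enrichmentScore(scores, sample(ids, size), p = p)$es, numeric(1))
  if (es == 0)
    return(list(es = 0, nes = 0, p_perm = 1, set_size = size,
                n_perm = n_perm))
  same <- if (es > 0) null_es[null_es >= 0] else null_es[null_es <= 0]
  if (!length(same)) {
    warning("all null enrichment scores have opposite sign; p at floor")
    return(list(es = es, nes = sign(es), p_perm = 1 / (n_perm + 1),
                set_size = size, n_perm = n_perm))
  }
  nes <- es / mean(abs(same))
  p_perm <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p_perm = p_perm, set_size = size, n_perm = n_perm)
}

#' Min-max scaled mean pathway expression
#'
#' Mean log2 LFQ intensity of each pathway's member proteins over the
#' control samples, then min-max scaled across the reported pathway
#' collection to [0, 1] — the "dot size" companion statistic of an
#' enrichment readout, reflecting how abundant a pathway is in the healthy
#' state.
#'
#' @param x a log2 \linkS4class{LfqExperiment}.
#' @param pathways named list: pathway id -> protein id vector; each must
#'   resolve to >= 1 measured protein.
#' @return named numeric in [0, 1]. A single pathway (or identical means)
#'   degenerates to 1.0 with a warning.
#' @export
scaledMeanExpression <- function(x, pathways) {
  stopifnot(is(x, "LfqExperiment"), length(pathways) >= 1)
  a <- lfqAssay(x)[, sampleGroups(x) == "control", drop = FALSE]
  means <- vapply(names(pathways), function(pw) {
    rows <- intersect(pathways[[pw]], rownames(a))
    if (!length(rows)) stop("pathway '", pw, "' has no measured proteins")
    mean(a[rows, ], na.rm = TRUE)
  }, numeric(1))
  rng <- range(means)
  if (diff(rng) == 0) {
    warning("degenerate min-max (single pathway or identical means); ",
            "scaled values set to 1")
    return(setNames(rep(1, length(means)), names(means)))
  }
  (means - rng[1]) / diff(rng)
}

#' Read gene sets from a GMT file
#'
#' One set per line: id, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}
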
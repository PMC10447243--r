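# Small builders shared across test files.

# LfqExperiment from an explicit matrix, control columns first.
makeLfq <- function(m, n_control, n_case, scale = "log2",
                    biosample = NULL) {
  colnames(m) <- colnames(m) %||%
    c(sprintf("ctl%d", seq_len(n_control)), sprintf("cas%d", seq_len(n_case)))
  LfqExperiment(m, group = rep(c("control", "case"), c(n_control, n_case)),
                biosample = biosample %||% colnames(m), scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force enrichment-score oracle: recompute the running sum at every
# prefix from scratch (no cumsum) and take the signed maximum deviation.
# Independent of the package's cumulative implementation.
bruteForceEs <- function(scores, gene_set, p = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  inset <- names(s) %in% gene_set
  N <- length(s)
  n <- sum(inset)
  if (n == 0 || n == N) return(0)
  denom <- sum(abs(s[inset])^p)
  best <- 0
  for (i in seq_len(N)) {
    pref <- seq_len(i)
    hit <- if (denom > 0)
      sum(abs(s[pref][inset[pref]])^p) / denom
    else sum(inset[pref]) / n
    miss <- sum(!inset[pref]) / (N - n)
    dev <- hit - miss
    if (abs(dev) > abs(best) + 1e-12) best <- dev
  }
  best
}

# Reference model with a case profile depleting TCA below ETC.
makeCaseProfile <- function(model, tca = 0.5, etc = 0.7) {
  prof <- setNames(rep(1, length(mappedProteins(model))),
                   mappedProteins(model))
  g <- defaultProteinGroups(model)
  prof[g$TCA] <- tca
  prof[g$ETC] <- etc
  prof
}
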
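test_that("technical replicate averaging follows the mean/missing rules", {
  m <- matrix(c(10, 12, NA, NA,
                1, 1, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("Pa", "Pb"), paste0("s", 1:4)))
  x <- LfqExperiment(m, group = c("control", "control", "case", "case"),
                     biosample = c("b1", "b1", "b2", "b2"))
  avg <- averageTechnicalReplicates(x)
  a <- lfqAssay(avg)
  expect_equal(unname(a["Pa", ]), c(11, NA))
  expect_equal(unname(a["Pb", ]), c(1, 1))
  # single observed value and all-missing propagate correctly
  m2 <- matrix(c(10, NA, NA, NA), 1,
               dimnames = list("P1", paste0("s", 1:4)))
  x2 <- LfqExperiment(m2, group = rep("control", 4),
                      biosample = c("b1", "b1", "b2", "b2"))
  a2 <- lfqAssay(averageTechnicalReplicates(x2))
  expect_equal(unname(a2[1, ]), c(10, NA))
})

test_that("replicates spanning different groups are an error", {
  m <- matrix(1, 1, 2, dimnames = list("P1", c("s1", "s2")))
  x <- LfqExperiment(m, group = c("control", "case"),
                     biosample = c("b1", "b1"))
  expect_error(averageTechnicalReplicates(x), "span different")
})

test_that("tier-1 imputation draws from the shifted, narrowed Gaussian", {
  # large matrix: >= 10,000 tier-1 cells; observed values at mu 25, sd 2
  set.seed(99)
  n <- 4000
  m <- matrix(rnorm(n * 12, 25, 2), n, 12)
  m[seq_len(2500), 1:6] <- NA          # control group < 50% detection
  m[seq(2501, 4000), 7:12] <- NA       # case group fully missing
  x <- makeLfq(m, 6, 6)
  obs <- m[!is.na(m)]
  imp <- imputeLfq(x, seed = 7)
  cells <- lfqAssay(imp$lfq)[imp$tiers == "shifted_gaussian"]
  expect_gte(length(cells), 10000)
  expect_lt(abs(mean(cells) - (mean(obs) - 2 * sd(obs))),
            0.02 * abs(mean(obs) - 2 * sd(obs)))
  expect_lt(abs(sd(cells) - 0.3 * sd(obs)), 0.02 * 0.3 * sd(obs))
})

test_that("a complete matrix passes through imputation unchanged", {
  m <- matrix(rnorm(40, 25, 2), 10, 4)
  x <- makeLfq(m, 2, 2)
  imp <- imputeLfq(x, seed = 1)
  expect_identical(lfqAssay(imp$lfq), lfqAssay(x))
  expect_true(all(imp$tiers == "none"))
})

test_that("a <50%-detected group is fully overwritten, the other untouched", {
  set.seed(3)
  m <- matrix(rnorm(200 * 11, 25, 2), 200, 11)
  m[1, 1:4] <- NA                       # protein 1: 2/6 control observed
  x <- makeLfq(m, 6, 5)
  before <- m
  imp <- imputeLfq(x, seed = 2)
  a <- lfqAssay(imp$lfq)
  expect_true(all(imp$tiers[1, 1:6] == "shifted_gaussian"))
  # the two observed control values were overwritten too
  expect_false(any(a[1, 5:6] == before[1, 5:6]))
  expect_identical(unname(a[1, 7:11]), before[1, 7:11])
  expect_true(all(imp$tiers[1, 7:11] == "none"))
  # restricting to missing cells preserves the observed ones
  imp2 <- imputeLfq(x, seed = 2, overwrite_observed = FALSE)
  expect_identical(unname(lfqAssay(imp2$lfq)[1, 5:6]), before[1, 5:6])
})

test_that("chained imputation fills sporadic missing cells plausibly", {
  set.seed(12)
  base <- rnorm(300, 25, 2)
  m <- base + matrix(rnorm(300 * 8, 0, 0.3), 300, 8)
  holes <- cbind(sample(300, 40), sample(8, 40, replace = TRUE))
  truth <- m[holes]
  m[holes] <- NA
  x <- makeLfq(m, 4, 4)
  imp <- imputeLfq(x, seed = 5)
  expect_false(anyNA(lfqAssay(imp$lfq)))
  filled <- lfqAssay(imp$lfq)[holes[imp$tiers[holes] == "chained", ,
                                    drop = FALSE]]
  # strong row structure: chained regression should track the truth
  err <- filled - truth[imp$tiers[holes] == "chained"]
  expect_lt(sqrt(mean(err^2)), 1)
  # observed cells are bit-identical
  keep <- imp$tiers == "none"
  expect_identical(lfqAssay(imp$lfq)[keep], lfqAssay(x)[keep])
})

test_that("imputation errors on degenerate input", {
  m <- matrix(25, 5, 4)
  m[1, 1] <- NA
  expect_error(imputeLfq(makeLfq(m, 2, 2)), "degenerate")
})

test_that("differential abundance matches the pooled t-test oracle", {
  m <- rbind(c(1, 2, 3, 4, 5, 6))
  rownames(m) <- "P1"
  x <- makeLfq(m, 3, 3)
  d <- differentialAbundance(x)
  # hand-computed pooled t: (5-2)/(1*sqrt(2/3)) = 3.674, df = 4
  expect_equal(d$log2fc, 3)
  expect_equal(d$t_stat, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(d$p_raw, 0.021312, tolerance = 1e-4)
  # independent routine: stats::t.test
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(d$t_stat, unname(tt$statistic))
  expect_equal(d$p_raw, tt$p.value)
})

test_that("identical group means give fc 0, p 1; Bonferroni caps at 1", {
  set.seed(8)
  m <- matrix(rnorm(1000 * 8, 25, 1), 1000, 8)
  m[1, ] <- rep(c(5, 6, 5, 6), 2)   # identical (5,6,5,6) in both groups
  x <- makeLfq(m, 4, 4)
  d <- differentialAbundance(x)
  expect_equal(d$log2fc[1], 0)
  expect_equal(d$p_raw[1], 1)
  expect_true(all(d$p_bonf <= 1))
  expect_equal(d$p_bonf, pmin(1, d$p_raw * 1000))
})

test_that("pca_qc separates groups and flags a displaced sample", {
  set.seed(44)
  m <- matrix(rnorm(100 * 8, 25, 0.1), 100, 8)
  m[1, 5:8] <- m[1, 5:8] + 50      # one protein separates the groups
  x <- makeLfq(m, 4, 4)
  qc <- pcaQc(x)
  expect_gt(qc$explained[1], 0.9)
  expect_true(all(qc$explained >= 0) && sum(qc$explained) <= 1 + 1e-8)
  expect_equal(colMeans(qc$coords), c(PC1 = 0, PC2 = 0), tolerance = 1e-8)
  # displaced sample
  m2 <- matrix(rnorm(100 * 8, 25, 0.5), 100, 8)
  m2[, 3] <- m2[, 3] + 10
  qc2 <- pcaQc(makeLfq(m2, 4, 4))
  expect_true(qc2$outliers[3])
  expect_equal(sum(qc2$outliers), 1)
  expect_error(pcaQc(makeLfq(matrix(1, 3, 2), 1, 1)), "3 samples")
})

test_that("complex-level ANOVA agrees with the independent routine", {
  y <- c(10, 10.5, 9.5, 12, 12.2, 11.8)
  m <- rbind(y, y)
  rownames(m) <- c("Pa", "Pb")
  x <- makeLfq(m, 3, 3)
  res <- complexLevelAnova(x, list(cx = c("Pa", "Pb")))
  ref <- summary(aov(y ~ g, data.frame(y = y,
                                       g = rep(c("c", "e"), each = 3))))
  expect_equal(res$F, ref[[1]][["F value"]][1])
  expect_equal(res$p, ref[[1]][["Pr(>F)"]][1])
  expect_warning(complexLevelAnova(x, list(empty = "Pzz")), "skipped")
})

test_that("two-group ANOVA F equals t squared", {
  set.seed(5)
  m <- matrix(rnorm(10 * 8, 25, 1), 10,
              dimnames = list(paste0("P", 1:10), NULL))
  x <- makeLfq(m, 4, 4)
  d <- differentialAbundance(x)
  av <- complexLevelAnova(x, as.list(setNames(rownames(m), rownames(m))))
  expect_equal(av$F, d$t_stat^2, tolerance = 1e-10)
})

test_that("ranking is ascending with lexicographic tie-break", {
  d <- data.frame(protein_id = c("Pb", "Pa", "Pc"),
                  log2fc = c(0, -2, 0))
  annot <- data.frame(protein_id = c("Pa", "Pb", "Pc"),
                      pathways = c("TCA", "", "TCA"))
  r <- rankByLog2fc(d, annot, "TCA")
  expect_equal(r$protein_id, c("Pa", "Pb", "Pc"))
  expect_equal(r$rank, 1:3)
  expect_equal(r$in_TCA, c(TRUE, FALSE, TRUE))
})

test_that("a planted depleted set ranks in the bottom quartile", {
  ids <- sprintf("P%04d", 1:20)
  d <- simDesign(n_control = 6, n_case = 6, n_proteins = 400,
                 pathways = list(TCA = ids),
                 effect_log2fc = setNames(rep(-1, 20), ids), seed = 13)
  sim <- simulateLfq(d)
  diff <- differentialAbundance(averageTechnicalReplicates(sim$lfq))
  r <- rankByLog2fc(diff, sim$annotation, "TCA")
  expect_lt(median(r$rank[r$in_TCA]), 100)
})

test_that("external correlation recovers exact and null relationships", {
  d <- data.frame(protein_id = paste0("P", 1:200),
                  log2fc = rnorm(200))
  expect_equal(correlateExternal(d, setNames(d$log2fc, d$protein_id))$r, 1)
  expect_equal(correlateExternal(d, setNames(-d$log2fc, d$protein_id))$r, -1)
  set.seed(10)
  r <- correlateExternal(d, setNames(rnorm(200), d$protein_id))
  expect_lt(abs(r$r), 0.2)
  expect_equal(r$n, 200)
  expect_error(correlateExternal(d, c(P1 = 1, P2 = 2)), ">= 3")
})
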
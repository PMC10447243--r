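# neuromito

Neuronal mitochondrial proteomics, in vivo biosensor quantification and
proteome-scaled bioenergetic modelling — an integrated, fully testable R
pipeline.

## The scientific problem

In neuroinflammatory lesions (e.g. the EAE mouse model of multiple
sclerosis), axons suffer an energy deficit whose origin is disputed: is it
a failure of oxidative phosphorylation itself, of the "upstream" TCA cycle
that feeds it redox substrate, or both? Answering this requires three
kinds of evidence to be processed consistently:

1. **LFQ proteomics** of immunocaptured neuronal mitochondria — replicate
   averaging, two-tier missing-value imputation, PCA quality control,
   per-protein differential statistics with Bonferroni control,
   complex-level ANOVA and external correlations;
2. **ratiometric biosensor imaging** of single axons and organelles
   (ATP/ADP, calcium, redox sensors) — background subtraction,
   three-region pixel-ratio quantification, FRET crosstalk correction
   (cFRET = acceptor − α·donor), control normalization, mean + 3 s.d.
   outlier classification, marker occupancy;
3. **kinetic modelling** of mitochondrial ATP production in which each
   maximal rate is scaled by measured protein abundance,
   *v*max(case) = *v*max(ref) × E(case)/E(mean control), ATP consumption
   follows the hyperbolic load law *v*ATP = *k*load · ATP/(ATP + *K*m),
   and protein groups (TCA cycle vs electron transport chain) can be
   "rectified" to control levels in silico to ask which is the more
   efficacious therapeutic target.

A seeded synthetic-data module generates every input with known ground
truth (planted fold changes, left-censored missingness, true sensor
ratios, crosstalk, abundance profiles), so each stage — and the whole
chain — is validated against construction rather than convention.

The package is written for computational biologists working at the
intersection of proteomics and neurobiology; it is Bioconductor-styled
(the central container extends `SummarizedExperiment`).

## Worked example

```r
library(neuromito)

ids <- sprintf("P%04d", 1:400)
design <- simDesign(n_proteins = 400,
                    pathways = list(TCA = ids[1:20], ETC = ids[21:50]),
                    effect_log2fc = c(setNames(rep(-1, 20), ids[1:20]),
                                      setNames(rep(-0.5, 30), ids[21:50])),
                    censor_quantile = 0.15, seed = 1)
sim <- simulateLfq(design)
sim$lfq
#> LfqExperiment: 400 proteins x 22 samples [ log2 scale ]
#>   groups: case=10, control=12
#>   missing cells: 1363 (15.5%)

imp  <- imputeLfq(averageTechnicalReplicates(sim$lfq), seed = 1)
diff <- differentialAbundance(imp$lfq, imp$tiers)
head(diff[order(diff$log2fc), c("protein_id", "log2fc", "p_bonf")], 3)
#>    protein_id    log2fc       p_bonf
#> 16      P0016 -1.655679 0.0008211174
#> 17      P0017 -1.388560 0.0222625379
#> 7       P0007 -1.370298 0.0018554935

scores <- setNames(diff$log2fc, diff$protein_id)
permutationNes(scores, ids[1:20], n_perm = 1000, seed = 2)[c("nes", "p_perm")]
#> TCA set: NES = -2.44, permutation p = 0.0013

steadyState(buildReferenceModel())
#> SteadyState (converged, residual 1.68e-14)
#>   ATP = 4.846 mM, ATP/ADP = 31.43 , psi = 174.7 mV
#>   v_ATP (load) = 1.658 mM/s
```

The most depleted proteins are members of the planted TCA set (their true
log2 fold change is −1; per-protein estimates scatter around it), the
enrichment module flags that set as significantly bottom-ranked
(NES < 0, permutation p ≈ 0.001), and the reference kinetic model rests at
an energized state (ATP/ADP ≫ 1, Δψ ≈ 175 mV) from which load titrations
and group rectifications start. `runPipeline(config, out_dir)` chains all
stages and writes a checksummed JSON manifest; identical config + seed
reproduces identical checksums.

## Documentation

The methods vignette (`vignettes/neuromito-methods.Rmd`) describes the
statistical models, the kinetic network and its calibration, every
convention adopted where the field leaves a choice open, and known
limitations.
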
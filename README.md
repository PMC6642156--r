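# nelcss

Quantitative secretome analysis of neuroendocrine (NE) lung cancer
subtypes from six-plex TMT proteomics, as a tested, reusable R pipeline.

Small cell lung cancer and related pulmonary NE tumors split into
subtypes driven by the transcription factors ASCL1 and NEUROD1. Proteins
these cells secrete (their *secretome*) are candidate blood biomarkers.
`nelcss` implements the full analysis path for a panel design in which NE
cancer cell lines are profiled against a normal bronchial epithelial
reference carried in every TMT set:

1. **Reporter quantification** — extract each TMT reporter ion as the
   maximum intensity in a 0.03 Th window around its theoretical m/z; sum
   reporter signal per protein ("SN"); equalize channel totals.
2. **PSM filtering** — score peptide-spectrum matches with a linear
   discriminant over Xcorr, ΔCn, missed cleavages, charge, mass accuracy,
   peptide length and fraction of matched ions, and filter to a 1%
   target-decoy FDR at peptide and protein level
   (threshold = lowest score with `#decoys/#targets ≤ level`).
3. **Integration** — fold changes `FC = SN(sample)/SN(reference)` per TMT
   set (replicate channels averaged), merged over commonly quantified
   proteins and restricted to plasma-detectable proteins.
4. **Signatures** — the pan-NE secretome signature (NE-LCSS):
   `AveFC ≥ 1.5` (up) or `≤ 1/1.5` (down) across all tumor lines with
   subtype balance `|log2(AveFC_ASCL1/AveFC_NEUROD1)| < 0.2`; and the
   subtype signature (AS/ND-LCSS) by a moderated t-test with
   empirical-Bayes variance shrinkage,

       s²_post = (d0·s0² + d_g·s²)/(d0 + d_g),
       t = Δmean / sqrt(s²_post·(1/n1 + 1/n2)),

   at Benjamini–Hochberg adjusted p < 0.05, split by effect sign.
5. **Validation** — complete-linkage hierarchical clustering with
   adjusted-Rand subtype concordance, `log2(1+FPKM)` / probe-averaging
   transforms, Welch t-tests, pairwise Pearson top-k driver-correlated
   gene ranking, one-sided Fisher enrichment, and E-box (CANNTG) motif
   scanning.

A synthetic-data module generates every input with known ground truth
(spectra with planted reporter peaks, target/decoy PSM tables, per-set
quantification tables with planted pan-NE and subtype markers, expression
matrices with planted driver-correlated genes), so the whole pipeline
runs and is tested without any external download. See the methods
vignette (`vignettes/nelcss-methods.Rmd`) for the model, the defaults and
their rationale, and known limitations.

## Worked example

```r
library(nelcss)
cfg <- pipeline_config(seed = 1, outdir = "demo_run")
rep <- run_pipeline(cfg)
```

which logs, stage by stage:

```
[nelcss:spectra] simulated 1000 spectra
[nelcss:psm] retained 4272 of 10000 PSMs at FDR 0.01
[nelcss:quant] 1000 proteins common across sets, 760 plasma-detectable
[nelcss:signature] NE-LCSS 47 up / 14 down; AS/ND-LCSS 220 proteins
[nelcss:validate] clustering ARI 1; top driver-correlated genes: G0836, G0679, G0129, G0265
```

Reading the numbers: all 6,000 planted reporter intensities were
recovered exactly; 4,272 of 10,000 simulated PSMs survive the 1%
target-decoy filter (most of the rest are decoys and planted false
matches); all 1,000 proteins are quantified in all three sets and 760 sit
on the synthetic plasma list; the duplicate reference channels correlate
at r = 0.99 (`rep$stages$quant$replicate_correlation_r`); and the
recovered subtype markers separate the 7 ASCL1-high from the 5
NEUROD1-high samples perfectly (adjusted Rand index 1). The signature
counts from this end-to-end run differ from the planted 58/18/65 because
fold changes are ratios to a per-set reference channel whose measurement
noise is shared within each set — an instructive property of the design
that the vignette discusses; deriving the signatures from fold-change
matrices with independent per-sample noise
(`simulate_fold_change_matrix()`) recovers the planted sets with ~98%
sensitivity:

```r
sim <- simulate_fold_change_matrix(sim_config(seed = 1))
ne <- derive_ne_lcss(sim$matrix)        # 1.5-fold + balance rule
asnd <- derive_asnd_lcss(sim$matrix)    # moderated t, BH < 0.05
print(ne)
#> NE-LCSS: 56 up / 17 down (AveFC >= 1.5 , |balance| < 0.2 )
print(asnd)
#> AS/ND-LCSS at adjusted p < 0.05 : 70 proteins ( 36 ASCL1-high / 34 NEUROD1-high )
```

Every run writes its artifacts (fold-change matrix, signature tables,
dendrogram in Newick, machine-readable `run_report.json`) under `outdir`;
identical seed and configuration reproduce byte-identical outputs. A thin
shell wrapper is included at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --seed 1 --outdir demo_run`, optionally
`--config pipeline.yaml`).

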
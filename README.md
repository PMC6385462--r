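# footprintr

Bias-aware transcription factor (TF) footprinting from DNase-seq and
ATAC-seq cut sites, at single-nucleotide resolution.

Both DNase I and the Tn5 transposase cut DNA with strong sequence
preferences: their relative hexamer propensities span two to three
orders of magnitude. A stretch of disfavored sequence therefore looks
exactly like a protein footprint. footprintr treats this enzyme bias as
the null model: candidate motif sites are scored by how much their cut
profile deviates from what the enzyme would do to naked DNA of the same
sequence, and replicate consistency decides which footprints are kept.

The package is aimed at regulatory-genomics analysts working with
DNase-seq or ATAC-seq who want site-centric footprint calls, and at
methodologists studying how protocol-specific sequence bias affects
footprinting.

## The method

1. **Cut-site tracks** (`extract_cut_sites`, `filter_fragments`,
   `filter_pcr_artifacts`): each read contributes one count at its 5'
   end — the actual cleavage/transposition site. Fragments outside
   38–1500 bp and PCR pile-ups (≥ 10 reads at one base making up ≥ 70%
   of the surrounding 30-bp window) are removed.
2. **Hexamer bias** (`estimate_kmer_bias`): from a deproteinized-DNA
   library, each k-mer's frequency among cut-centered k-mers is divided
   by its genomic frequency. A value of 1 means no bias.
   `strand_symmetry_report` checks that plus- and minus-read-derived
   tables agree, justifying one shared table.
3. **Candidate sites** (`scan_genome`): every window on both strands is
   scored as log P(sequence | PWM) − log P(sequence | first-order
   Markov chain fitted on the local 500-bp window); the top 50,000
   matches are kept. `empirical_pvalue` calibrates the weakest match.
4. **Footprint model** (`build_site_matrix`, `build_backgrounds`,
   `fit_em`, `flr`): cut counts in each site ± 25 bp are modelled as a
   two-component multinomial mixture — a shared footprint component,
   re-estimated by EM, against a fixed per-site background equal to the
   site's bias-expected cut profile (or uniform, for the uncorrected
   variant). Each site gets a footprint log-likelihood ratio
   FLR = log P(x | footprint) − log P(x | background); FLR > 0 means
   "more bound than bias".
5. **Reproducible footprints** (`idr_fit`, `flr_idr_select`): sites with
   positive FLR in both replicates are ranked, a Gaussian copula mixture
   estimates the irreproducible discovery rate, and the list ranked by
   mean FLR is truncated at the count passing global IDR ≤ 0.01.
6. **Evaluation** (`cv_auc`, `model_similarity`, `signal_to_noise`,
   `sensitivity_specificity`): fourfold cross-validated AUROC/AUPR
   against ChIP-seq labels, footprint-background similarity, and peak
   signal-to-noise.

A seeded simulator (`simulate_genome`, `simulate_bias_table`,
`plant_sites`, `simulate_naked_cuts`, `simulate_site_counts`,
`simulate_cuts`) generates genomes, bias tables, and replicate cut data
with known ground truth, so the entire pipeline is testable without any
download.

## Worked example

Simulate a 400-kb genome with 500 bound and 1,500 unbound motif sites
under a strongly biased ATAC-like enzyme, fit the mixture, and score:

```r
library(footprintr)
genome  <- simulate_genome(c(chr1 = 4e5), seed = 1)
bias    <- simulate_bias_table(seed = 2)
bias
#> kmer_bias_table: k=6, protocol=ATAC, range [0.00613, 83.5]

motif   <- pwm(matrix(c(12,1,1,1, 1,12,1,1, 1,1,12,1, 1,1,1,12, 12,1,1,1,
                        1,12,1,1, 1,1,12,1, 1,1,1,12, 12,1,1,1, 1,1,1,12),
                      4, 10), name = "simTF")
planted <- plant_sites(genome, motif, n_bound = 500, n_unbound = 1500,
                       seed = 3)
shape   <- footprint_shape(ncol(motif), preset = "atac")
counts  <- simulate_site_counts(planted$sites, planted$genome, shape, bias,
                                depth = 50, overdispersion = 1.3,
                                seed = 4)[[1]]

bg    <- build_backgrounds(planted$sites, planted$genome, "bias", bias)
model <- fit_em(counts, initialize_footprint(counts, planted$sites$bound),
                bg)
model
#> footprint_model: W=60, pi=0.274, 3 EM iteration(s), converged

scores <- flr(counts, model)
summary(scores[planted$sites$bound])    # bound:   median FLR  35.8
summary(scores[!planted$sites$bound])   # unbound: median FLR -28.3
sensitivity_specificity(scores, planted$sites$bound)
#> $sensitivity 0.988   $specificity 0.957

cv_auc(counts, bg, planted$sites$bound, folds = 4, seed = 5)
#> eval_report: 2000 sites (500 positive), 4-fold CV: AUROC 0.994, AUPR 0.978
```

The fitted mixture weight (`pi = 0.27`) is close to the planted bound
fraction (0.25); bound and unbound sites separate by roughly 60 FLR
units at median; and the decision rule FLR > 0 recovers 98.8% of bound
sites at 95.7% specificity. With the uniform (uncorrected) background
the same data give a cross-validated AUROC of 0.979 — bias correction
closes most of the remaining gap to perfect separation, and the
advantage widens as the enzyme's bias gets more confounding (the
acceptance run measures a gap of ~0.11 under its conditions).

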
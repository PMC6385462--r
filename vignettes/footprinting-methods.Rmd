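---
title: "Bias-aware TF footprinting: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware TF footprinting: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The problem

A transcription factor (TF) bound to DNA shields its binding site from
nucleases. In DNase-seq and ATAC-seq, each sequenced read 5' end marks a
single cleavage (DNase I) or transposition (Tn5) event, so a bound site
appears as a local depletion of cut events — a *footprint* — inside an
otherwise accessible region. The catch is that both enzymes cut
non-uniformly: their sequence preferences span two to three orders of
magnitude across hexamers, so a stretch of disfavored sequence produces a
footprint-shaped dip with no protein anywhere near it. footprintr
implements a site-centric, single-nucleotide-resolution footprinting
pipeline in which this enzyme bias *is* the null model.

## Cut-site conventions

A cut counted at base $b$ is modelled as the event in the gap immediately
5' of $b$ on the read's strand: gap coordinate $b$ for plus-strand reads
and $b + 1$ for minus-strand reads. The associated k-mer is the genomic
window $[p - k/2,\, p + k/2)$ around the gap $p$, read on the cut's
strand (reverse complement for minus-strand cuts), so the event falls
between the third and fourth base of a hexamer. Under this convention the
two cuts of a blunt double-strand event see reverse-complementary
hexamers, which is what justifies one shared bias table for both strands.
The conventional ATAC +4/−5 shift (re-centering counts on the 9-bp Tn5
duplication) is available via `extract_cut_sites(shift_mode =
"plus4_minus5")` but is not the default: the unshifted 5' end is the
cleavage site itself, and keeping it preserves the strand symmetry of the
hexamer model.

Read-level filters follow standard practice: proper pairs with fragment
length in the inclusive 38–1500 bp range (`filter_fragments`), and a PCR
pile-up filter (`filter_pcr_artifacts`) that zeroes any base holding at
least 10 strand-summed counts when those counts make up at least 70% of
the surrounding 30-bp window. The 30-bp window is taken as
$[b-15, b+15)$; the pile and window totals are computed on pooled
(strand-summed) counts, since a PCR artifact duplicates a specific
fragment regardless of which mate is inspected.

## The hexamer bias model

`estimate_kmer_bias` divides each hexamer's relative frequency among
cut-centered hexamers (from a deproteinized, "naked" DNA library) by its
relative frequency in the genome (both strands, optionally restricted to
a mappability mask). A pseudo-count of one cut per hexamer keeps
propensities strictly positive — required downstream, where they become
multinomial parameters. If a hexamer is absent from the background
genome, a pseudo-frequency of one occurrence is added to every hexamer
and a warning raised; with genomes above ~100 kb this path is never
taken. N-containing k-mers are excluded from estimation; in
`expected_cut_profile` a position whose k-mer contains N receives the
table's geometric-mean propensity and the profile is flagged.

`strand_symmetry_report` estimates one table from plus-strand cuts only
and one from minus-strand cuts only and reports the Pearson correlation
of log10 propensities. Two facts are worth separating. The *estimator* is
exactly symmetric: on a palindromic genome with mirrored cuts the two
tables are identical (a unit test asserts correlation 1 to 1e-12). The
*sampled* correlation, however, is depth-limited: each strand-specific
table rests on its own cut events, and at $10^5$ total cuts a hexamer
receives ~12 events per strand, a Poisson noise floor that caps the
correlation near 0.9 regardless of the true bias spread. At $10^6$ cuts
the correlation exceeds 0.97. Published libraries are one to two orders
deeper still, which is why a single shared table is justified in
practice.

## Candidate sites: PWM scanning

`scan_genome` scores every window of motif length on both strands as
$\log P(\text{window} \mid \text{PWM}) - \log P(\text{window} \mid
\text{background})$, where the background is a first-order Markov chain
estimated from the 500-bp window centered on the candidate position
(clipped at chromosome ends). A pseudocount of 0.0005 is added to every
PWM frequency and columns are renormalized, keeping each column a proper
distribution. Transition counts receive add-one smoothing over the 16
transitions. The local background is estimated strand-symmetrically —
window counts plus their reverse complement — so one model serves both
strands of a locus; as a consequence a palindromic PWM scores the two
strands equally up to edge terms of the local window (tested at
tolerance 0.05) rather than exactly. The top 50,000 sites are retained by
default; overlapping matches are kept, and score ties at the cutoff are
all retained. Per-position background re-estimation is the default; a
`block_size` argument reuses one background per block as a speed option,
which changes scores by well under 1% of their range.

`empirical_pvalue` calibrates a motif set's weakest match: sequences are
simulated from the PWM (positives) and from a first-order Markov chain
fitted to user-supplied background sequence such as hypersensitive sites
(negatives); the negative-score quantile at each false-positive rate on a
grid down to $10^{-6}$ gives a cutoff, and the grid point closest to the
observed minimum score is reported with its FPR as the empirical p value.
The sample size must be at least $10/\mathrm{FPR}_{\min}$.

## The footprint mixture model

Each candidate site is taken with 25-bp flanks ($W = L + 50$ positions)
and its strand-summed cut counts form one row of the site matrix;
minus-strand sites are reversed so position 1 is always the motif's 5'
flank. Two multinomials over the $W$ positions compete for each site:

* a **footprint** component, shared across sites, initialized from the
  aggregate profile of sites overlapping ChIP-seq peaks for the factor
  and re-estimated by EM;
* a **background** component per site, fixed during EM: either the
  bias-expected profile of the site's own sequence (weights proportional
  to the hexamer propensity centered on each gap, normalized to 1) or a
  uniform $1/W$ profile for the no-correction variant.

The E-step computes the footprint responsibility of each site from the
multinomial likelihoods and mixture weight $\pi$; the M-step re-estimates
the footprint as the responsibility-weighted column sum (pseudocount 0.5)
and $\pi$ as the mean responsibility. Multinomial coefficients are
omitted throughout — they cancel in both responsibilities and scores.
Backgrounds are floored at $10^{-8}$ and renormalized. Convergence is a
relative log-likelihood change below $10^{-6}$ (cap 200 iterations,
$\pi$ initialized at 0.5), and the log likelihood is asserted
non-decreasing. With `fixed_background = FALSE` a single shared
background is re-estimated instead; per-site re-estimation is
deliberately not offered, as it would let the background absorb the
footprint.

The footprint log-likelihood ratio of a site is
$\mathrm{FLR} = \log P(x \mid f) - \log P(x \mid b_i)$: positive when the
cut profile looks more bound than bias-expected. The mixture prior-odds
term $\log(\pi/(1-\pi))$ is excluded by default — "log odds of footprint
vs. background" is read as a likelihood ratio, and a constant offset
would not change any ranking — but `include_prior_odds = TRUE` adds it.

## Reproducibility: IDR on FLR rankings

With two replicates, sites with positive FLR in both are ranked, a
two-component Gaussian copula mixture is fitted to the rank pairs
(correlated component = reproducible; independent standard component =
irreproducible), and sites re-ranked by mean FLR are truncated at the
count whose global IDR — the running mean of sorted local idr values —
passes 0.01. The same machinery (`idr_fit`, `truncate_joint_list`)
serves peak lists ranked by signal.

The copula EM uses rank pseudo-values re-mapped through the current
marginal, moment updates for (p, mu, sigma², rho), and two structural
safeguards motivated by model-intrinsic degeneracies:

* at the null (independent replicates) the two components coincide and
  the reproducible fraction p sits on a likelihood ridge; a weak
  parsimony prior (2% pseudo-observations) resolves the ridge toward
  small p, so null data pass nothing instead of an arbitrary fraction;
* sigma² is floored at 0.3 because near-duplicate rank pairs otherwise
  trigger the classic Gaussian micro-cluster collapse, with the
  "reproducible" component shrinking onto a handful of top sites.

Initialization is p = 0.5, mu = 1, sigma² = 1, rho = 0.5; ties get
average ranks; outer convergence is declared when parameters move by
less than $10^{-3}$. Verified behavior: duplicated rankings give p ≈
0.98 with every site passing; independent rankings pass nothing; a
planted mixture (fraction 0.6, rho 0.8, N = 5000) is recovered within
±0.1 (the rank transform compresses the estimate slightly, to ~0.55).

## Evaluation

`cv_auc` performs stratified fourfold cross-validation: the model is
initialized and fitted on three folds and the held-out fold is scored by
FLR against its own backgrounds; AUROC and AUPR (rank statistic with
mid-rank ties; trapezoidal PR integration) are averaged over folds. The
fold seed is mandatory and logged. `model_similarity` is the Pearson
correlation between the fitted footprint and the mean background
profile; against an exactly uniform background the correlation is
undefined (zero variance), and the function returns 0 with a
`degenerate` attribute rather than failing, because the uniform variant
is a supported mode. `signal_to_noise` is
$\log_2(\text{mean in-peak count} / \text{mean count in 300-bp
flanks})$. `sensitivity_specificity` evaluates calls at FLR > 0.

## The simulator: what it emulates and what it does not

All tests and the acceptance script run on synthetic data with known
truth, produced by seeded generators:

* **Genome and sites** — i.i.d. bases at a chosen GC content;
  PWM-sampled site sequences spliced in at non-overlapping loci (jitter
  bounded so padded windows stay disjoint), with recorded strands and
  bound/unbound labels.
* **Bias tables** — a flat table with `n_hot = 40` hexamers elevated
  8-fold and log-normal noise of sd 1.25 (natural log) on all entries,
  spreading propensities over roughly two to three decades, the span
  reported for DNase I and Tn5 hexamer preferences. For the ATAC protocol
  the table is made reverse-complement symmetric (one draw per rc pair),
  the palindromic preference expected of a homodimeric enzyme.
* **Naked digests** — cut gaps sampled with probability proportional to
  the propensity of their centered hexamer, independently per strand; a
  `paired` mode deposits each event's plus cut and its mirrored minus cut
  together, emulating the strand symmetry of a double-strand
  transposition event.
* **Site counts** — the generative model mirrors the two-component
  multinomial mixture: bound sites draw from the footprint shape, unbound
  sites from their own sequence's bias-expected profile, partial
  occupancy from the convex mixture. Presets: `"dnase"` protection
  confined to the motif; `"atac"` protection extending ~10 bp beyond the
  motif with shoulder peaks (residual cutting 0.15 of open flanks).
  Replicates are independent multinomial draws. A per-site log-normal
  depth factor shared across replicates (CV parameter `overdispersion`)
  models the heavy-tailed spread of site accessibility; log-normal was
  chosen over gamma because gamma with CV > 1 puts its mode at zero and
  extinguishes sites, which real accessibility does not. A configurable
  fraction of unbound sites (`spurious_frac`, default 0.15) shows a transient
  partial footprint whose strength (uniform below 0.65) fluctuates
  independently between replicates — the irreproducible population that
  replicate selection exists to remove, without which the IDR model is
  degenerate by construction.

What the simulator does **not** emulate: mappability structure, copy
number, nucleosome positioning, fragment-length structure (reads are
reduced to cut events), chromatin-driven smoothness beyond the hexamer
model, and enzyme bias beyond k-mers. Passing tests therefore show that
the estimators recover the model they assume under realistic noise — not
that the hexamer model fully describes any particular real library.

## Problem sizes and numerical choices

The test suite and acceptance script use: 1-Mb genomes with $10^6$ naked
cuts for bias recovery (log10 Pearson ≈ 0.994); 2,000 sites at depth 50
for EM recovery (footprint total variation ≈ 0.015, $\pi$ within 0.02 of
0.4); 24 simulated TFs, varying the motif's hexamer propensities
100-fold, for the similarity-performance association (consistently
negative, ≈ −0.4); and 10,000 candidate sites (1,000 bound) for
replicate selection. The end-to-end FLR-IDR run uses a deep-library
condition of ~800 cuts per 61-bp site window — plausible for the top
candidate sites of a few-hundred-million-read library — because at mean
depth 50 the FLR's multinomial sampling noise caps within-bound replicate
rank concordance near 0.91 while a 1% IDR pass requires ~0.98; at depth
50 the selection is near-perfectly precise but recovers only about half
of the bound sites, a depth limitation of the statistic rather than a
failure of the selection rule.

## Known limitations

Single shared footprint multinomial per factor (no per-site shape
variation); two components only; per-site backgrounds fixed during EM;
two-replicate IDR only; no gapped-k-mer bias models; the scanner's local
Markov background makes cross-strand palindrome symmetry approximate at
window edges. The simulator's generative mixture matches the fitted
model's family, which is the appropriate setting for parameter-recovery
claims but flatters the model relative to real chromatin.
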
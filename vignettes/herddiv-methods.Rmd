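---
title: "Pedigree and genomic diversity analysis with herddiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree and genomic diversity analysis with herddiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herddiv)
```

# The problem

Small, closed livestock populations — local cattle breeds kept by a few
herds, conservation nuclei, tropical creole breeds — lose genetic
diversity quickly when few sires dominate reproduction. The questions a
breed association needs answered are concrete: how inbred is the herd,
how fast is inbreeding accumulating, how many founders and ancestors
effectively contributed to today's animals, what is the effective
population size now and what was it historically, where in the genome has
selection (or drift) fixed haplotypes, and is inbreeding already
depressing performance?

`herddiv` answers all of these from the three files such populations
typically have: a pedigree (often incomplete), SNP-chip genotypes for a
modest subset of animals, and field-recorded weights. Because real herd
books are usually confidential, the package also ships a simulator that
produces pedigrees, gene-dropped genotypes and phenotypes with known
ground truth; every analysis in the package is validated against that
truth or against an independent oracle.

# Pedigree metrics

**Inbreeding (F).** The probability that the two alleles at a locus are
identical by descent, computed by the Meuwissen–Luo algorithm, which
accumulates the diagonal of the additive relationship matrix A animal by
animal over its ancestor list without ever storing A. Unknown parents
contribute nothing, so F is a lower bound under incomplete recording —
the simulator's `missing_sire`/`missing_dam` switches let you quantify
that underestimation directly. `additiveRelationshipMatrix()` builds the
full tabular A for moderate pedigrees and serves as the package's own
cross-check (the two implementations agree to 1e-10 in the test suite).

**Relatedness (AR).** An animal's mean additive relationship to the whole
pedigree, halved: the probability that a random allele from the
population belongs to that animal. Computed in linear time via
A = TDT': one reverse sweep for T'1, a diagonal scaling by the Mendelian
sampling variances, one forward sweep for the final product.

**Pedigree depth.** Equivalent complete generations
EqG = Σ (1/2)^n over all known-ancestor paths, and the per-generation
completeness index (the proportion of filled ancestor slots at each
depth, e.g. 0.75 when three of four grandparents are known). We count an
ancestor once per path, which makes EqG of an animal with both parents
known exactly 1 regardless of deeper structure.

**Generation intervals.** A record is a parent's age at the birth of an
offspring that itself reproduced, assigned to the four selection paths
(sire–sire … dam–dam) by the offspring's sex. The pooled interval is the
record-level mean, i.e. the count-weighted mean of the path means —
pooling published path tables with `poolGenerationIntervals()` uses the
same rule. Offspring of unknown sex are excluded and counted rather than
guessed.

**Realized Ne.** Individual rates ΔF_i = 1 − (1 − F_i)^(1/(EqG_i − 1))
are averaged and inverted: Ne = 1/(2 mean ΔF). Animals with EqG ≤ 1 have
a degenerate exponent and are excluded (their count is reported). The
standard error comes from the delta method,
SE(Ne) = SD(ΔF)/√N · 1/(2 mean²), which yields the symmetric normal
confidence interval `neConfidenceInterval()` reports; this reproduces
the way such intervals are printed in the herd-book literature.

**Probabilities of gene origin.** Founder contributions q_k are genome
weights passed up the pedigree (each reference animal contributes 1/n,
half per parent line); unknown single-parent slots become phantom
founders, so Σq = 1 and fe = 1/Σq². The effective number of ancestors
uses Boichard's marginal-contribution algorithm: repeatedly select the
candidate with the largest contribution *not yet explained*, then cut its
parent links so weight flowing through it is absorbed. Two design points
were genuinely open and are fixed as follows:

* a candidate's arriving weight is discounted by the expected fraction of
  its own genome already explained by the selected set (computed by one
  downward pass per round) — without this, a descendant of a chosen
  ancestor would be credited for genes already counted;
* candidates are animals with progeny, plus reference animals with an
  unknown parent slot (nobody else can explain those genome halves).
  This keeps Σp = 1 at exhaustion and makes fa equal fe exactly when
  every ancestor is a founder with non-overlapping descent, the
  no-bottleneck limiting case. Ties are broken by pedigree record order,
  which keeps runs bit-reproducible.

# Genomic inbreeding

**GRM.** VanRaden's G = ZZ'/(2Σp(1−p)) with missing dosages imputed to
2p. FGRM = diag(G) − 1. The default fixes every allele frequency at 0.5
(`freq = "fixed_half"`), the right choice when the genotyped subset is
far too small to estimate frequencies; in that mode, complete genotypes
give the exact identity FGRM = 1 − 2·(heterozygous fraction), and
negative values simply flag animals more heterozygous than the 0.5
expectation.

**Runs of homozygosity.** The consecutive method: per animal and
chromosome, a run of homozygous calls breaks at any heterozygote, any
missing call, and any inter-marker gap above 1 Mb; it is kept when it has
≥ 15 SNP *and* spans ≥ 1 Mb (`rohConfig()`). Coordinates are
SNP-anchored (first to last SNP, 1-based closed); length in Mb is
(end − start)/1e6. FROH divides the summed run length by the autosomal
map length LAUT (map extents by default; a published constant can be
supplied for replication). Length classes are half-open with inclusive
lower edge — a run of exactly 2.000 Mb belongs to 2–4 Mb — and FROH at
threshold x uses runs of at least x Mb, so the thresholded series is
monotone by construction. Heterozygosity runs (`detectROHet()`) use the
same scan with a 250 kb span, tolerating at most 3 homozygous and 2
missing interior calls; a run must start and end on a heterozygote, a
violation closes it at the last heterozygote, and scanning resumes at
the next one — a deterministic reading of the loosely specified
"consecutive" tolerance semantics.

**Shared runs and islands.** Specific ROH group runs with *exactly* equal
coordinates (a deliberately strict criterion: on chip data, identical IBD
haplotypes produce identical SNP anchors). Island scans compute per-SNP
incidence (carriers / genotyped animals), cut at a percentile of the
incidence distribution (default 99.9 as the convention reads, even
though "top 0.01%" would be the 99.99th — the parameter is exposed), and
report maximal contiguous above-threshold stretches that do not span a
gap over 1 Mb.

# LD and historical Ne

r² is the squared Pearson correlation of dosage vectors over animals
complete at both loci, for same-chromosome pairs between 100 kb and
35 Mb, averaged in 30 log-spaced distance bins (log spacing covers recent
and distant generations evenly; linear binning would starve the short
distances). The sampling-bias adjustment subtracts 1/(βn) with β = 1 for
unphased data. Distance maps to recombination rate by Sved–Feldman
c = d(1 − d/2) (Haldane and linear mappings are available), dated
t = 1/(2c), and inverted as Ne(t) = (1/r²adj − α)/(4c) with α = 2 to
absorb mutation. Bins whose adjusted r² is at or below the noise floor
(non-positive, or implying non-positive Ne) are dropped with a warning
rather than reported. Feeding the closed form r²adj = 1/(4Nc + α) back
through the pipeline returns N exactly, which the tests assert to 1e-9.

# The simulator and what passing tests mean

`simPedigree()` builds discrete generations with a sire-usage skew and
three mating schemes (random, assortative-by-relationship,
full-sib lines); true F is computed on the complete pedigree *before*
parent masking, so estimated-vs-true comparisons are exact.
`simGenotypes()` gene-drops labelled founder haplotypes with Haldane
crossovers at 1 cM = 1 Mb and records realised IBD, so FROH and FGRM can
be checked against true autozygosity; dosages are recoded to count the
observed minor allele, matching the PLINK reader convention.
`simWrightFisher()` (C++ inner loop) provides the constant-size benchmark
for the LD pipeline. `simPhenotypes()` adds sex, year and a linear
inbreeding effect in kg per 1% F.

Default scales were chosen once to mirror a small tropical beef herd: a
few dozen founders, 4–6 generations, 25% of males used as sires, missing
parent rates around 10–35%, birth weights near 27 kg (residual SD 4 kg)
and weaning weights near 144 kg, depression slopes of −0.103 and −0.685
kg per 1% F. The validation suite runs at desk scale (tens of animals ×
a few thousand SNP; Wright–Fisher at N = 100, 20 chromosomes × 200 SNP,
200 generations, samples of 50; depression recovery at n = 1300 with 200
replicates) — sizes picked as the smallest at which the stochastic
recoveries are stable.

What the simulator does *not* emulate: genotyping-cluster artefacts,
allele-frequency spectra shaped by ascertainment, selection during the
pedigree, age-structured overlapping generations, and non-linear
(dominance-epistatic) depression. Passing tests therefore demonstrate
correctness of the estimators under their own model assumptions, not
robustness to chip artefacts.

# Phenotype QC and the depression model

Weaning records are first windowed to 240 ± 45 d of age, then adjusted to
240 d by the linear-gain rule WW240 = BW + 240(WW − BW)/age (falling back
to WW·240/age without a birth weight), and only then passed through the
±3 SD filter — applied once, with mean and SD from the pre-filter data,
so the operation is idempotent and order-stable. The depression model is
ordinary least squares, y = μ + sex + year + β₁F + e, with F as a
fraction and β₁ reported per 1% (coefficient/100). Rank-deficient
birth-year classes are merged into a pooled level and logged instead of
silently dropping records. The power contrast the tests reproduce — a
−0.1 kg/% slope detected at n ≈ 1300 but mostly non-significant in
subsamples of 50 — is the statistical reason genotyped-subset regressions
come out non-significant in small herds.

# Numerical choices and degenerate inputs

* Cycles and duplicate ids are construction-time errors; named parents
  without records are promoted to founders.
* Unknown-parent tokens default to `"0"`, `""`, `"NA"` and are
  configurable in `readPedigree()`.
* Minor alleles are defined from observed post-missing frequencies; a
  tie at 0.5 is broken by allele lexical order.
* QC order is fixed (autosomes → animal call rate → marker call rate →
  MAF (strictly greater) → HWE exact test, no mid-p) and idempotent;
  removing every marker or animal is a hard error.
* Zero-variance loci are dropped from observed-frequency GRMs with a
  warning; with fixed 0.5 frequencies they are retained (they carry
  homozygosity information).
* All generators take a mandatory seed; a pipeline run writes a manifest
  of digests, and reruns with the same seed are byte-identical.

# Known limitations

The tabular A matrix is dense (quadratic memory), intended for
cross-checks rather than national evaluations. The Boichard candidate
rule above is one defensible reading of "ancestors"; a rule that also
admits terminal non-founder reference animals would trade the
fa ≤ fe guarantee for slightly larger explained fractions in shallow
pedigrees. LD-based Ne inherits the usual caveats: the distance-to-time
mapping assumes 1 cM = 1 Mb unless told otherwise, and estimates at
distant generations lean on short-distance bins where the α correction
matters most. Confidence intervals for Ne(t) are deliberately not
produced.
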
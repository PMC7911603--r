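# herddiv

Pedigree and genomic diversity analysis for small, partially genotyped
livestock populations.

Small closed herds — local and creole cattle breeds in particular — lose
genetic diversity fast when a handful of sires dominate reproduction.
`herddiv` is for the people who monitor that: breed associations, herd-book
curators and animal-breeding researchers who have an (often incomplete)
pedigree, SNP-chip genotypes for a few dozen animals, and field-recorded
weights, and who need the standard battery of diversity diagnostics from
those three files.

## What it computes

**Pedigree metrics.** Inbreeding *F* (Meuwissen–Luo algorithm; equals
`diag(A) − 1` of Wright's numerator relationship matrix), relatedness
*AR<sub>i</sub>* = (1/2n) Σ<sub>j</sub> a<sub>ij</sub>, equivalent complete
generations EqG = Σ (1/2)<sup>n</sup> over known-ancestor paths, pedigree
completeness per ancestral generation, generation intervals by the four
selection paths with record-level pooling, realized effective population
size

> Ne = 1 / (2 ΔF̄),  ΔF<sub>i</sub> = 1 − (1 − F<sub>i</sub>)<sup>1/(EqG<sub>i</sub> − 1)</sup>

with a delta-method standard error, and probabilities of gene origin: the
effective number of founders f<sub>e</sub> = 1/Σq<sub>k</sub>² and of
ancestors f<sub>a</sub> = 1/Σp<sub>k</sub>² (Boichard marginal
contributions); f<sub>a</sub>/f<sub>e</sub> < 1 flags bottlenecks.

**Genomic inbreeding.** VanRaden's GRM G = ZZ′/2Σp(1−p) with
F<sub>GRM</sub> = diag(G) − 1 (allele frequencies fixable at 0.5 for small
genotyped sets), and runs of homozygosity by the consecutive method (≥ 15
SNP, ≥ 1 Mb, no heterozygous/missing call, gaps ≤ 1 Mb) with
F<sub>ROH</sub> = L<sub>ROH</sub>/L<sub>AUT</sub>, length classes, per-
chromosome F<sub>ROHCHR</sub>, exactly-shared segments, plus
heterozygosity runs (≥ 15 SNP, ≥ 250 kb, ≤ 3 homozygous and ≤ 2 missing
inside) and incidence-percentile islands for selection signatures.

**Historical Ne from LD.** Binned r² decay, the 1/(βn) sampling
adjustment, Sved–Feldman mapping c = d(1 − d/2), t = 1/(2c), and

> Ne(t) = (1/r²<sub>adj</sub> − α) / (4c),  α = 2.

**Inbreeding depression.** Phenotype QC (age windowing, 240-d adjustment,
±3 SD filter) and OLS of weights on F with sex and birth-year fixed
effects, reported in kg per 1 % inbreeding.

**Simulator.** Multi-generation pedigrees (random / assortative /
full-sib mating, sire-usage skew, parent masking), gene-dropped SNP
genotypes with exact IBD bookkeeping, a Wright–Fisher forward simulator
(C++), and phenotypes with a known depression slope — the ground truth the
test suite validates against.

## Worked example

```r
library(herddiv)
sim <- simPedigree(n_founders = 40, n_generations = 5, n_offspring = 80,
                   prop_sires = 0.1, missing_dam = 0.15, seed = 42)
ped <- sim$pedigree
F   <- inbreedingCoef(ped)
eqg <- equivalentGenerations(ped)
ne  <- realizedNe(F, eqg)
ref <- referencePopulation(ped)
fe  <- effectiveFounders(ped, ref); fa <- effectiveAncestors(ped, ref)
sg  <- simGenotypes(sim, n_chromosomes = 10, snp_per_chrom = 500,
                    chrom_length_mb = 100, seed = 43)
gd  <- qcGenotypes(sg$genotypes)$genotypes
s   <- summarizeROH(detectROH(gd), gd)
fit <- fitDepression(
  qcPhenotypes(simPhenotypes(ped, F, traits = "birth_weight", seed = 44)),
  F, "FPED")
```

which prints (seeds as above):

```
mean F = 8.28% | mean EqG = 2.37 | Ne = 8.6 (95% CI 7.8-9.3)
fe = 5.6 | fa = 5.5 | fa/fe = 0.98 | top 2 ancestors explain 50%
3773 ROH in 440 animals | mean FROH = 10.13% | class shares: 0.4% 16.4% 30.9% 29.7% 22.5%
Inbreeding depression: birth_weight on FPED
  beta1 = -0.1079 +/- 0.0313 kg per 1% inbreeding (p = 0.000613, n = 439)
```

Read it as a diagnosis: two sires per generation drive the realized Ne to
8.6 — far below the ~50 usually cited as the minimum for maintaining
diversity — and mean inbreeding to 8.3 % within five generations;
effectively five-and-a-half founders contribute; ten percent of the
genotyped animals' autosomes sit in runs of homozygosity, most of it in
long (> 4 Mb, recent-inbreeding) segments; and each 1 % of inbreeding
costs about 0.11 kg of birth weight, recovering the simulated −0.103.
`runPipeline(out_dir, seed)` runs the same stages end to end and writes
every table plus a digest manifest.

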
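---
title: "Meiotic behavior of doubled-diploid parents from tetraploid progeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meiotic behavior of doubled-diploid parents from tetraploid progeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrazyg)
```

## The problem

Citrus rootstock breeders cross tetraploid parents ("tetrazyg" breeding)
that arose by chromosome doubling of interspecific diploid hybrids. Such a
doubled diploid carries two identical copies of each of its two divergent
homologs, so its meiosis sits between two extremes:

* **disomy** — identical homologs always pair; every diploid gamete is
  heterozygous for the two parental haplotypes, no interspecific
  recombination is visible;
* **tetrasomy** — pairing is random; a duplex locus A1A1A2A2 yields the
  diploid gamete classes A1A1, A2A2, A1A2 with probabilities 1/6, 1/6, 4/6,
  so heterozygosity drops to 66% (without double reduction).

Where a parent sits on that axis decides how much parental heterozygosity
its gametes transmit, how much interspecific recombination a breeder can
exploit, and how much power a dose-phenotype association scan has.
`tetrazyg` implements the whole analysis chain from genotypes of the
tetraploid progeny back to these meiotic parameters, together with a
simulator that generates cohorts with known truth.

## The model

### Gamete classes and preferential pairing

Per chromosome and meiosis the simulator draws a pairing configuration:
homologous bivalents with probability $1 - 2\tau/3$ and each of the two
heterologous configurations with probability $\tau/3$, where
$\tau \in [0,1]$ is the *tetrasomic parameter* and $\mathrm{PP} = 1-\tau$
the *preferential pairing*. This mapping is chosen because it reproduces
the centromeric gamete class probabilities of a duplex locus exactly:

$$P(A_1A_1) = P(A_2A_2) = \tau/6, \qquad P(A_1A_2) = 1 - \tau/3 .$$

The pairing literature specifies these gamete probabilities, not the
pairing mechanism itself; any mechanism reproducing them is observationally
equivalent at one locus. Because each bivalent transmits either partner
with probability 1/2 at every position, the class probabilities above hold
at *every* locus under this model, not only at the centromere — real
meioses, with partner switches along the chromosome, violate this, which
is why PP should be estimated at centromeric markers (where double
reduction is also negligible) and why the estimator here follows that
practice.

`estimate_tau()` maximizes the log-likelihood
$(x_1+x_2)\log(\tau/6) + x_3\log(1-\tau/3)$ over a grid of step 0.005
(ties toward smaller $\tau$; the combinatorial constant is dropped). The
maximizer has the closed form $\hat\tau = \min(1,\, 3(x_1+x_2)/N)$, which
the test suite uses as an independent oracle over an exhaustive sweep of
count triples. `pp_per_chromosome()` estimates $\tau$ at the window
nearest the supplied centromere midpoint plus its two flanking windows and
averages the three PP values. With $N$ gametes the estimate carries a
binomial standard error of $3\sqrt{p(1-p)/N}$, $p = \tau/3$ — about
0.03–0.045 at $N = 1000$ — which is why the recovery checks in the test
suite assess the *bias* of the estimator across replicate cohorts rather
than a single draw.

### Crossovers

Crossover counts per bivalent are Poisson with mean twice the chromosome's
genetic length in Morgans, positions uniform, no chromatid or crossover
interference, each crossover picking one random chromatid of each partner.
A transmitted chromatid then carries the configured map length on average.
Double reduction is structurally impossible (bivalents only), matching the
no-double-reduction assumption of the estimators.

### Diagnostic SNPs and GST

Taxon-diagnostic SNPs are mined from reference accessions with the
one-versus-rest differentiation statistic
$G_{ST} = (He_{Tot} - (He_{T_i} + He_{T_{-i}})/2)/He_{Tot}$, with
$He = 1 - \sum p_i^2$ and the total-population frequency taken as the
unweighted mean of the two subpopulation frequencies (equal taxon
weights). Sites with more than 20% missing genotypes are excluded first;
a site is diagnostic when $G_{ST} = 1$ (tested with tolerance $10^{-9}$).
Monomorphic sites have no defined $G_{ST}$ and are skipped — the statistic
is 0/0 there, and treating it as 0 would silently absorb them. Het
genotypes contribute 0.5 to taxon allele frequencies (plain allele
counting).

### Window dosing

Single GBS-depth SNPs cannot resolve tetraploid allele dosage, so doses
are called per window of 20 diagnostic SNPs: reads are pooled across the
member sites and the dose $d \in \{0..4\}$ maximizing
$\mathrm{Binomial}(a \mid t, f_d)$, $f_d = \mathrm{clamp}(d/4, \epsilon,
1-\epsilon)$, is called. Pooling is the simplest statistic consistent with
a multilocus read count over phased markers. Calls are withheld when the
window has fewer than 10 reads (mirroring the coverage-10 genotype filter
of GBS SNP calling) or when the best dose beats the runner-up by less than
one log10 likelihood unit. A terminal window remainder of at least 10
DSNPs stays its own window, smaller remainders merge into the previous
window. No smoothing is applied along chromosomes; singleton cleaning
plays that role downstream.

### Gamete inference and cleaning

In this cross only one parent contributes each tracked ancestor
(*C. medica* through the ovule, *P. trifoliata* through the pollen), so
hybrid doses 0–2 are the gamete doses verbatim and doses 3–4 are flagged
inconsistencies. Cleaning then proceeds: singletons (an interior call
differing from both agreeing non-missing flanks) become missing; windows
with more than 15% missing calls are dropped, then individuals with more
than 20%; finally individuals whose apparent-recombination transition
count exceeds `median + 3*IQR` of the cohort are removed — a robust,
automatic stand-in for the visual inspection of the global recombination
distribution that a human analyst would do, and configurable. Cleaning
only ever adds missingness.

### Segregation deviation and FDR

Per window, observed class counts are tested against the tetrasomic
expectation $(N/6, N/6, 4N/6)$ with a 2-df chi-square; q-values are
Benjamini–Hochberg by default (threshold 0.05). Storey-style q-values
(BH scaled by $\hat\pi_0 = \min(1, 2\,\overline{[p > 0.5]})$) are exposed
behind `q_method = "storey"` because the FDR literature the field cites
includes both procedures; BH is the more conservative, fully reproducible
default.

### Recombination fractions: two estimators, two jobs

The apparent ("dose") estimator
$\hat r = \sum_g |d_i(g) - d_j(g)| / (2N)$ counts visible ancestry changes
between windows: exact for single-crossover intervals, blind to
recombination between identical homologs. Maps built from it therefore
shrink with preferential pairing, which is precisely the biology — the
apparent map length of a fully disomic chromosome is zero.

That same blindness makes the dose estimator unusable for linkage
grouping: for *independent* windows its expectation is
$E|d_i - d_j|/2 \approx 0.28$ at $\tau = 1$ (and lower at smaller
$\tau$), never the 0.5 an unlinked pair should show, so no threshold can
separate linked from unlinked. Under the bivalent model the dose
*correlation* between linked windows is $1 - 2r$ whatever $\tau$ (pairing
scales covariance and variance identically) and ~0 for unlinked pairs,
so `linkage_groups()` uses $\hat r = (1 - \max(\mathrm{cor}, 0))/2$ with
single-linkage clustering at threshold 0.3. `build_map()` keeps physical
marker order (the reference assembly order is taken as correct; no
reordering is attempted), accumulates Kosambi distances
$25\ln\frac{1+2r}{1-2r}$ over adjacent windows, and assigns zero length
with a warning where the adjacent rf is missing or at the 0.5 cap (where
Kosambi diverges).

`marey_rate()` is a local linear regression of cM on Mb with tricube
weights over a span of 0.15 of each group's markers (at least 4), the
local slope being the recombination rate in cM/Mb with negative slopes
clipped to 0 — a loess-type smoother written out explicitly because the
slope, not the fitted value, is the quantity of interest.

### Association and gene inheritance

`glm_scan()` fits `phenotype ~ dose` per window with additive 0/1/2
coding and an F test (factor coding available), skipping monomorphic
windows and annotating significance at p < 0.01 — the printed
significance statement in the source material reads "p > 0.01", which we
take as a typo for "p < 0.01". `gene_inheritance()` maps gene intervals
onto overlapping windows (majority vote across windows; ties and missing
calls are undetermined) and tabulates per-gene dose percentages plus the
fraction of hybrids carrying at least one tracked-ancestor dose at every
supplied gene.

## What the simulator emulates — and what it does not

The generator reproduces: the four-ancestor design (reticulata/medica
ovule parent; trifoliata against a reticulata/maxima mosaic pollen
parent, doubled); per-chromosome preferential pairing defaulting to the
published per-chromosome PP values of the two rootstocks; 96 hybrids;
Poisson GBS-like depth (default 20) with per-read error 0.01 and 2%
missing sites; and diagnostic-SNP panels whose 20-SNP windows are ~100 kb
wide — the physical window width of a dense real panel — while keeping a
desk-scale number of windows (10 per chromosome). Chromosome lengths
(26–50 Mb) and the 3 cM/Mb genetic scale are one-time realistic choices.

It does **not** emulate: quadrivalents or double reduction, pairing-partner
switches along a chromosome (class frequencies are exact at all loci, see
above), crossover interference, segmental losses of somatic hybrids,
reference-alignment artifacts, or sequence-level reads. Passing tests
therefore demonstrate correctness of the estimators under the bivalent
model, not robustness to those real-data complications.

The citrumelo reticulata/maxima alternation breakpoints are not published;
the default mosaic switches at 40% and 80% of each chromosome and is
configurable.

## Numerical choices

* `tetrasomic_probs()` computes the heterozygous class as $(3-\tau)/3$,
  algebraically identical to $1-\tau/3$ but exact in floating point at
  $\tau = 1$ (bit-for-bit 2/3).
* The $\tau$ grid includes both endpoints; at $\tau = 0$ the homozygous
  term is $-\infty$ when $x_1 + x_2 > 0$ and 0 otherwise, and ties break
  toward smaller $\tau$ (`which.max` takes the first maximum).
* Dose likelihoods clamp $f_d$ to $[\epsilon, 1-\epsilon]$, so dose 0 and
  4 remain distinguishable from read error.
* PCoA uses classical double-centering (`stats::cmdscale`); variance
  shares are taken over positive eigenvalues only.
* Degenerate inputs: empty panels, all-missing windows, chromosomes with
  fewer than three windows, and non-symmetric dissimilarity matrices are
  errors; all-dropped matrices after filtering are fatal rather than
  silently empty.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely on simulated data:
50,000 (script) / 40,000 (tests) gametes for the tetrasomic heterozygosity
floor; an exhaustive (s, x3) sweep of all class-count triples with
N ≤ 200 against the closed-form oracle; 5 cohorts of 1000 gametes per PP
level for recovery bias; 20 replicates of 500 windows × 96 gametes for
FDR control; 40 hybrids × 3 chromosomes at depth 30 for pipeline
inversion; 96 gametes × 9 chromosomes at $\tau = 0.5$ (the genome-wide
average of the less disomic parent) for synteny; and 50 replicates of 100
gametes, $\tau = 1$, for QTL recovery — $\tau = 1$ maximizes dose variance,
mirroring the observation that strong preferential pairing is what
cripples QTL detection in these populations.

## A short worked example

```{r example, eval = FALSE}
cfg <- default_config()
co  <- simulate_cohort(cfg, seed = 1)
doses <- call_hybrid_doses(co$counts, co$partition)
gam <- clean_gametes(infer_gametes(doses$medica, "ovule"))$matrix
fit <- meiosis_fit(gam, co$centromeres)
summary(fit)
coef(fit)          # per-chromosome preferential pairing
plot(fit)          # PHR and deviation q-values along the genome
map <- build_map(gam)
marey_rate(map)
```

`run_pipeline(cfg, outdir = "run1", seed = 1)` executes all stages and
writes every intermediate as TSV/CSV/JSON next to the resolved
configuration, so a run is fully inspectable and re-runnable.

## Known limitations

* The PP estimator assumes a duplex locus and no double reduction; it is
  not meaningful away from centromeres on real data.
* The dose rf estimator undercounts double crossovers within an interval;
  at 20-DSNP window resolution this is negligible, at coarser resolution
  it is not.
* Linkage grouping needs segregating windows: a chromosome with PP
  exactly 1 produces constant dose columns and cannot be grouped (its
  windows carry no linkage information at all).
* The association scan is a plain per-window GLM without kinship or
  structure correction, matching the original design; with strong
  preferential pairing the dose classes are heavily unbalanced and power
  is intrinsically low.
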
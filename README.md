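# tetrazyg

Meiotic behavior of allotetraploid (doubled-diploid) parents, inferred from
genotyping of their tetraploid sexual progeny.

Citrus rootstock breeders cross tetraploid parents that arose by chromosome
doubling of interspecific diploid hybrids ("tetrazyg" breeding). How such a
parent pairs its chromosomes at meiosis — preferentially between identical
homologs (disomy) or at random (tetrasomy) — decides how much parental
heterozygosity its diploid gametes transmit, how much interspecific
recombination is available to selection, and how much power a
dose-phenotype association scan has. `tetrazyg` implements the full
analysis chain for a cross between two doubled diploids genotyped by
sequencing, plus a meiosis simulator with complete ground truth:

* **Diagnostic SNP mining** — one-vs-rest GST with equal taxon weights;
  `GST = (HeTot − (HeTi + HeT−i)/2)/HeTot`, `He = 1 − Σ p²`; a site is
  diagnostic when GST = 1.
* **Ancestral dosing** — per genomic window of 20 diagnostic SNPs, the
  dose `d ∈ {0..4}` maximizing the pooled binomial likelihood
  `B(a | t, clamp(d/4, ε, 1−ε))` of the window's diagnostic-allele reads.
* **Gamete inference and cleaning** — gamete doses read off hybrid doses
  (each tracked ancestor enters through one parent only), singleton
  replacement, 15%/20% missing-data filters, robust removal of
  aberrant-recombination individuals.
* **Meiotic-behavior fit** (`meiosis_fit()`, a classed model object with
  `print`/`summary`/`coef`/`plot`/`residuals`/`simulate` methods) —
  parental heterozygosity restitution (PHR); preferential pairing
  `PP = 1 − τ̂` by grid-search ML of
  `L(τ) ∝ (τ/6)^(x1+x2) (1 − τ/3)^x3` at the three centromeric windows
  (grid step 0.005); per-window chi-square deviation from the tetrasomic
  expectation `(N/6, N/6, 4N/6)` with Benjamini–Hochberg q-values.
* **Maps and recombination landscapes** — apparent recombination fractions
  `Σ|Δdose|/(2N)`, Kosambi map distances `25·ln((1+2r)/(1−2r))` on fixed
  physical order, correlation-based linkage grouping, Marey-map local
  recombination rates (tricube local regression, span 0.15), Manhattan
  dissimilarity + principal coordinates.
* **Association** — per-window GLM `phenotype ~ dose` (additive 0/1/2
  coding, F test) and candidate-gene ancestor-dose inheritance tables.
* **Simulator** — doubled-diploid bivalent meiosis with per-chromosome
  tetrasomic parameter τ (homologous pairing with probability `1 − 2τ/3`,
  reproducing gamete classes `τ/6, τ/6, 1 − τ/3`), Poisson crossovers, no
  double reduction; read counts and additive QTL phenotypes.

## Worked example

Simulate the default synthetic cohort (96 hybrids, nine chromosomes,
per-chromosome PP of the two study rootstocks), call window doses from
read counts, infer and clean the ovule gametes, and fit the meiotic model:

```r
library(tetrazyg)
cfg   <- default_config()
co    <- simulate_cohort(cfg, seed = 1)
doses <- call_hybrid_doses(co$counts, co$partition)
gam   <- clean_gametes(infer_gametes(doses$medica, "ovule"))$matrix
fit   <- meiosis_fit(gam, co$centromeres)
summary(fit)
```

```
Meiotic behavior fit (95 gametes, 90 windows, ancestor medica)
  genome PHR 0.847, genome PP 0.546, 77.8% windows deviate from tetrasomy (q < 0.05)

Per-chromosome meiotic parameters:
 chrom n_windows   phr    pp mean_neg_log10_q n_significant pct_significant
  chr1        10 0.881 0.652            4.069            10             100
  chr2        10 0.966 0.905            7.417            10             100
  chr3        10 0.674 0.057            0.047             0               0
  chr4        10 0.886 0.628            4.168            10             100
  chr5        10 0.659 0.025            0.245             0               0
  chr6        10 0.862 0.612            3.325            10             100
  chr7        10 0.942 0.820            6.361            10             100
  chr8        10 0.925 0.735            5.779            10             100
  chr9        10 0.826 0.482            2.340            10             100
```

One of 96 individuals was removed by the cleaning chain (95 gametes). The
fitted per-chromosome PP tracks the simulated truth (0.583, 0.81, 0.317,
0.548, 0, 0.675, 0.663, 0.672, 0.25): chromosome 5, simulated fully
tetrasomic, is estimated at PP ≈ 0.03 with no significant deviation from
tetrasomic segregation and the lowest PHR (0.66, near the 2/3 tetrasomic
floor), while the strongly disomic chromosome 2 restores 97% of parental
heterozygosity. The apparent genetic map shows the same biology inverted —
recombination is visible only when unlike homologs pair:

```r
build_map(gam)
```

```
Genetic map: 90 markers in 9 linkage groups, total 150.52 cM
 chrom n_markers length_cm
  chr2        10  2.631793   # PP 0.90  -> almost no visible recombination
  chr5        10 37.724961   # PP 0     -> longest apparent map
  ...
```

`run_pipeline(cfg, outdir = "run1", seed = 1)` executes every stage
(mining → dosing → inference → meiotic fit → maps/Marey/PCoA →
association → gene inheritance) and writes all intermediates as
plain-text TSV/CSV/JSON next to the resolved `config.yaml`.

See the methods vignette (`vignettes/allotetraploid-meiosis.Rmd`) for the
model, estimators, defaults and limitations.

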
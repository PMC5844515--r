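---
title: "Models and methods behind recombean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind recombean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

recombean reconstructs, as a tested pipeline, the classical analysis of
recombination rate and linkage disequilibrium (LD) in a selfing crop
genome: a recombinant inbred line (RIL) linkage map is built from
biallelic marker calls, markers are anchored to the physical map through
sequence-similarity hits, Marey maps turn the two coordinate systems
into a recombination landscape with pericentromeric (pCENR) plateau
calls, and a structured diversity panel supplies genepool-stratified
diversity and LD statistics. The package is modeled on the common bean
(*Phaseolus vulgaris*) BAT93 x Jalo EEP558 mapping population (an
advanced F11 RIL population genotyped with 768 gene-based SNP assays on
11 chromosomes) and its companion diversity panel of 71 Andean and 115
Mesoamerican inbred genotypes. Because the original genotype calls were
never deposited, a seeded synthetic-data generator stands in for them;
every statistical stage is exercised against data with known truth.

## Two-point RIL mapping

A line is informative for a marker pair when both calls are homozygous
(`A`/`B`); heterozygous calls - rare at F11 - and failed calls are
excluded pairwise, following the treatment of heterozygotes as missing
in array-based RIL genotyping. With $n$ informative lines of which
$n_R$ are recombinant, the observed fraction is $\hat R = n_R/n$ and
the LOD score is

$$\mathrm{LOD} = n_R \log_{10}\frac{\hat R}{0.5}
  + (n - n_R)\log_{10}\frac{1-\hat R}{0.5},$$

with the $\hat R = 0$ limit $n \log_{10} 2$. Repeated selfing lets
recombinant chromosomes accumulate, so the line-level fraction
overstates the meiotic one; the Haldane-Waddington relation
$R = 2r/(1+2r)$ is inverted ($r = R / (2(1-R))$, capped at 0.5) before
any map-distance computation. Distances use the Kosambi function
$d = 25\,\ln\frac{1+2r}{1-2r}$ cM, matching the mapping software the
design emulates.

Grouping is single-linkage transitive closure over pairs with
LOD $\ge$ 6 (the published grouping threshold) and corrected
$r \le 0.4$. Ordering minimizes the sum of adjacent recombination
fractions (SARF) by greedy path growth plus 2-opt reversal, then a
multipoint "ripple" polish: an exhaustive permutation of a sliding
4-marker window that minimizes the total number of crossover
breakpoints implied by the genotype matrix. The ripple step goes beyond
the plain SARF/2-opt design because two-point statistics cannot see
double-recombinant evidence; breakpoint parsimony is the criterion the
emulated best-order/ripple workflow uses. Ties (orders with equal
breakpoint counts) keep the SARF order, so results are deterministic.

A caveat quantified during development: with ~700 markers and 200
lines, roughly 1-2% of truth-adjacent marker pairs have no realized,
observed recombinant line at all. For those pairs the two candidate
local orders are exactly likelihood-equivalent - we verified that the
estimated and true orders imply identical breakpoint counts - so no
ordering algorithm can resolve them, and order-recovery accuracy
plateaus near 98.5-99.5% depending on the seed. Crossover interference
(absent from the generator, see below) would reduce such ties in real
data.

## Physical anchoring

Markers are placed from alignment hits using the best-hit rule: a
marker is unplaced if its lowest E-value exceeds 1e-30, a singleton if
the next-best E-value is at least 1e10 times the best (the "difference
of e^-10" read as a multiplicative separation, since E-values live on a
log scale), and multiple otherwise. The physical position is the
midpoint of the best hit's subject interval. Real analyses should
import 12-column tabular hits from a production aligner;
`naive_search()` exists so synthetic genomes can be anchored
end-to-end. It seeds on exact 11-mers, extends ungapped over the full
query with the blastn default +2/-3 match/mismatch scores, and converts
scores to E-values with the corresponding ungapped Karlin-Altschul
constants ($\lambda = 0.625$, $K = 0.41$). It only needs to rank hits
correctly on synthetic data; it is not a replacement for a real
aligner. Marker-gene correspondence uses half-open interval
intersection (at least one shared base), the same semantics as the
standard genome-arithmetic tools.

## Marey maps and the recombination landscape

Each chromosome's Marey curve pairs the map position (cM) with the
physical position (bp) of its singleton-placed markers, oriented so the
two increase together. A least-squares polynomial is fitted and its
values projected to the nearest non-decreasing sequence (isotonic
adjustment), so the derivative - the local recombination rate in
cM/Mb - is never negative. The default degree is 7: a cubic can draw a
single sigmoid, but its derivative is a parabola and cannot hold a long
near-zero plateau between two steep arms; at typical marker densities
the degree-7 fit recovers simulated plateau intervals with mean Jaccard
0.75-0.88 where the cubic scores below 0.1.

pCENR detection uses a two-level rule on the rate profile: a plateau
exists wherever the rate drops below 10% of the genome-wide mean
("almost no recombination"), and its boundaries extend to the crossing
of 50% of the mean. The polynomial necessarily rounds the plateau
shoulders, and the mid-level crossing of a smoothed step is the natural
estimator of the true edge; with the 10% floor alone only the plateau
core is called.

The landscape summary reports per-chromosome genetic/physical ratios
(cM/Mb, two decimals, half-up rounding to match published tables), bp
per cM, and two genome-level rates that are deliberately distinct: the
ratio of summed map length to summed physical length, and the mean (with
population SD) of the per-chromosome ratios. `bean_reference_map()`
ships the published per-chromosome table for the reference bean map,
including its printed totals row - which does not equal the column sums
(the refined per-chromosome distances sum to 1046.9 cM against a printed
total of 1097.5) - so the published summary statistics can be recomputed
from the table exactly as printed.

## Diversity and LD statistics

Inbred lines are counted as single alleles. Per marker and scope
(global, or within a genepool) the package reports the minor allele
frequency, polymorphic information content
$\mathrm{PIC} = 1 - (p^2+q^2) - 2p^2q^2$, and per-site nucleotide
diversity $\pi = \frac{n}{n-1} 2p(1-p)$. The folded site-frequency
spectrum bins MAF into ten equal classes on $[0, 0.5]$. The neutral
expectation draws each segregating site's derived count $i$ with
probability $\propto 1/i$ (the standard Wright-Fisher frequency
spectrum), folds, bins, and repeats 5,000 times for a mean and a
2.5-97.5% envelope; this is equivalent in expectation to coalescent
simulation for unlinked sites and much faster.

Pairwise LD treats the inbred genotypes as haplotypes and reports
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$, and
$r^2 = D^2/(p_Aq_Ap_Bq_B)$, with a two-sided Fisher exact p-value
computed by the point-probability method (summing hypergeometric
probabilities no larger than the observed table's). The algebraic
bound $r^2 \le D'^2$ holds for every pair. Markers enter LD analysis
only with MAF strictly above 0.05 and call rate at least 80%.

LD decay restricts to same-linkage-group pairs, by default those with
Fisher $p < 0.001$, and fits both a quadratic polynomial and an
exponential $a e^{-bd} + c$. The decay distance (default threshold
$r^2 = 0.1$) is read from the polynomial - the regression model named
for this purpose - because the significance screen floors the
$r^2$ of every retained distant pair at the per-sample-size
significance limit (about 0.15 at $n = 71$), which an exponential's
non-negative asymptote cannot descend through even when LD has fully
decayed. The exponential is reported as the tendency line when its
F-test against a constant model is significant, with its own crossing
when one exists. Binned means are exported for plotting, and the
directional comparison between genepools is run without the p-screen
(all same-group pairs), where the crossing is well defined.

## Sliding windows

Windows of 1 Mb every 200 kb tile each chromosome from position 0;
the gene count uses any-overlap semantics (containment available), the
window recombination rate is the Marey-fit genetic span divided by the
window width (cM/bp), and mean $r^2$ (in percent) averages pairs whose
two markers both fall inside the window. Pearson and Spearman
correlations are reported with the caveat that overlapping windows are
dependent; p-values are deliberately uncorrected, reproducing the
usual sliding-window practice.

## The synthetic-data generator

The generator defines the study conditions everything above is tested
under.

**Genome.** Eleven chromosomes spanning ~32-60 Mb with one
pericentromeric interval each covering 40% of the chromosome at 5% of
the arm recombination intensity; the ninth chromosome is telocentric
(plateau at the chromosome start), mirroring the one telocentric
chromosome of the bean karyotype. The arm intensity default (3.4
cM/Mb) makes the genome-wide average ~2.1 cM/Mb, the published
genome-wide rate. Markers emulate gene-based SNP assays: close to
evenly spaced on the genetic scale (jittered quantiles of the
intensity measure), hence concentrated in the recombining, gene-dense
arms - the published maps describe exactly this even spacing. Gene
models are placed with density proportional to recombination
intensity, so gene-dense windows carry high recombination by
construction.

**RIL population.** Each line descends from an F1 by
generation-by-generation selfing (default to F11); every meiosis drops
crossovers as a Poisson process on the genetic scale without
interference (the estimation stage, not the generator, applies
Kosambi). The default population size is 80 lines, typical for this
reference population; parameter-recovery experiments use 200. Missing
calls (2%) and a residual heterozygosity target (0.5%, the published
upper bound; natural F11 heterozygosity counts toward it) are applied
last.

**Diversity panel.** A hierarchical haplotype-clade model: each marker
has an ancestral frequency split into two deep clades (Balding-Nichols
drift 0.9), so clades are near-fixed and markers sharing a clade block
are in near-complete LD. Genepools diverge by lineage sorting - a
`divergence` fraction (default 0.4, reflecting the strong published
genepool split for assays ascertained between genepool parents) of
markers re-drawn per pool clade. Races within a pool share clade
content but differ in clade *usage* (a race-specific usage probability
drawn from a symmetric Beta): pooling usage-biased races inflates LD at
all distances, which is how race substructure slows LD decay in real
germplasm. Individuals are block mosaics of the two clades along the
genetic map with 30 cM correlation length, calibrated together with
the clade depth so within-genepool LD decays to $r^2 = 0.1$ on the
20-30 cM scale reported for domesticated bean. Defaults give the
Andean pool one race and the Mesoamerican pool three (its substructure
is described as more extensive), sizes 71 and 115.

What the generator does **not** model: domestication bottlenecks or
other demography, selection, gene conversion, crossover interference,
genotyping error beyond missingness/heterozygosity, and ascertainment
of specific marker panels. Passing tests therefore show that the
estimators recover the parameters of this generative model at the
study's scale - not that every published number would reproduce from
the undeposited real data.

## Numerical and design choices

- All simulators draw from a private RNG stream seeded explicitly;
  the global RNG state is never disturbed, and identical seeds give
  byte-identical outputs.
- Problem sizes in the test-suite experiments: parameter recovery uses
  three replicates of 11 chromosomes x ~700 markers x 200 lines;
  decay-direction checks use 5 chromosomes x 350 markers and five
  panel seeds; the neutral-SFS check uses 5,000 repetitions of 10,000
  markers at sample size 10.
- Ties in marker ordering break toward the lower marker index and the
  output orientation is canonicalized, so every map is reproducible.
- Degenerate inputs are handled explicitly: pairs with fewer than two
  informative lines return an uninformative sentinel; $r \ge 0.5$ is
  capped at 50 cM with a warning; duplicate physical positions are
  averaged before Marey fitting; chromosomes shorter than one window
  yield a single truncated, flagged window; zero-margin contingency
  tables have $p = 1$.
- Internal coordinates are 0-based half-open; GFF3 and tabular-hit
  coordinates (1-based inclusive, minus-strand hits with start > end)
  are converted at the boundary and restored on write.
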
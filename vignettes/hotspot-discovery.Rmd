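---
title: "Signature-associated hotspot discovery: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-associated hotspot discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sighotspot)
```

## The problem

Cancer driver mutations are hard to recognise outside coding exons,
where recurrence alone is weak evidence. `sighotspot` takes a different
route: it asks whether the tumors carrying mutations at a genomic
hotspot show systematically shifted *exposure* to a mutational
signature — a probability distribution over substitution context
classes that characterises a mutagenic process (APOBEC cytidine
deamination, spontaneous CpG deamination, somatic hypermutation, and so
on). A hotspot whose carriers are enriched for a process, and which
falls in a coding or regulatory element, is a candidate driver shaped
by that process; one without functional context is a susceptible
target of the process.

## Mutation catalogs and context classes

Every somatic single-nucleotide variant is assigned to one of 96
classes: 6 pyrimidine-strand substitution types (C>A, C>G, C>T, T>A,
T>C, T>G) times 4 five-prime times 4 three-prime flanking bases.
Purine-reference substitutions are reverse-complemented before
classification. Two flank conventions are supported:

* **trinucleotide** — the immediate neighbours (positions −1/+1), the
  standard COSMIC SBS convention;
* **NxSxN** — the bases two positions away (−2/+2), obtained by
  collapsing the 1536 full penta-nucleotide classes
  (6×4×4×4×4) over the immediate neighbours. Each NxSxN class is the
  sum of exactly 16 penta classes (`reduce_penta_to_nxsxn()`), so
  catalogs are conserved. The NxSxN view captures longer-range
  sequence preferences (for example of APOBEC enzymes) at the same
  96-class complexity.

Class ordering everywhere follows the conventional COSMIC
lexicographic order, so published signature TSVs drop in directly.

## Exposure assignment

Per tumor, exposures $e \ge 0$ minimise $\lVert c - e^\top S\rVert_2$
where $c$ is the 96-class count vector and $S$ the signature matrix;
the solution is found by active-set non-negative least squares and
then row-normalised to proportions. No sum-to-one constraint is
imposed during optimisation — normalisation afterwards is equivalent
for proportions and keeps the quadratic program unconstrained beyond
positivity. Zero-mutation tumors get all-zero exposure rows. A tumor
is *positive* for a signature when its normalised exposure strictly
exceeds 5%. Externally estimated exposure tables can be supplied via
`read_exposures()` when a different assigner is preferred.

## Window scan and hotspot pruning

The genome is tiled with half-overlapping 2 kb windows at 1 kb steps,
starting at coordinate 1 per chromosome; the final partial window is
retained if it meets the variant minimum. Windows with fewer than 6
variants are discarded. Within a candidate window, variants are binned
into 30 bp sub-windows at 15 bp steps (an interior variant lies in
exactly two sub-windows), each tumor contributing with weight
$w_t = 1/\log_2 V_t$, where $V_t$ is the tumor's total somatic SNV
load ($V_t < 2$ is clamped to 2 with a warning). With the weighted
load $L_i = \sum_t w_t\, l_{it}$, sub-window $i$ is a hotspot when all
of

$$L_i \ge \max(L)/2, \qquad L_i > 3\,\overline{L}, \qquad
  L_i \ge \overline{L} + 3\,\mathrm{sd}(L)$$

hold. `sd` is the sample (n−1) standard deviation — the default of the
language the rule was designed in; a single-sub-window vector is
treated as sd 0. The rule is scale-free, so rescaling all weights
changes nothing. Member sites of selected sub-windows are keyed by
(chromosome, position, alternate allele): recurrence counts tumors
sharing position *and* substitution, since signature association is
substitution-specific (a position-only mode is available by flag).

Entity restriction precedes the scan: in normal mode only entities
with ≥5% signature-positive tumors are tested (2% in wide mode).

## The association test

Eligible hotspots (top recurrence ≥6, or total variants ≥10 with top
recurrence ≥3) are tested with a covariate-adjusted kernel score test.
The null model is ordinary least squares of the normalised exposure on
intercept, entity (one-hot), mutational load (`nvar`) and sex;
degenerate single-level factors are dropped with a warning, and the
`unknown` sex level is a legitimate category. Each site carries weight
$R \times \mathrm{median}(L_{\text{carriers}})$ — recurrence times the
median load of its carriers (even-count medians by midpoint).

On the null residuals the test evaluates the mixture statistic
$Q_\rho = (1-\rho)\,Q_{\text{SKAT}} + \rho\,Q_{\text{burden}}$ over
the grid $\rho \in \{0, 0.1^2, \dots, 0.9^2, 1\}$ — the standard
optimal-test grid; the mixing parameter is an implementation choice,
not part of the published rule. Per-$\rho$ p-values come from the tail
of a weighted chi-square mixture and the omnibus p-value from the
one-dimensional integration over the minimum-p statistic (the SKAT-O
construction). The omnibus statistic is sign-free, so the reported
direction is the sign of the weighted burden score — negative
associations are biologically meaningful (a process can avoid a
locus).

**Quadratic-form tails.** $P(\sum_k \lambda_k \chi^2_{1,k} > q)$ is
computed by numerically inverting the exact characteristic function
(Imhof's integral) with a composite Gauss–Legendre rule: segments of
at most one sine period, graded near $u = 0$ where
$\arctan(\lambda_{\max} u)$ varies fastest, truncated where a
twice-integrated-by-parts bound falls below the target accuracy
(1e-9 by default). A mixture with equal weights is a scaled
chi-square and is evaluated in closed form. Probabilities below about
1e-8 are beyond the resolution of double-precision inversion; there,
and when the quadrature fails, a four-moment (Liu-style) chi-square
match is used, which preserves ordering in the far tail. This mirrors
the Davies-with-Liu-fallback convention of rare-variant testing
practice.

**Single-site hotspots.** For one site the score is a simple linear
statistic of the residuals and the residual-permutation law — the
test's own calibration target — has closed-form moments. The
single-site p-value therefore uses the exact permutation moments
(second through fourth, derived from index-partition sums and verified
against exhaustive enumeration) with a symmetric Edgeworth tail
correction; in the far tail, where conditional corrections are
negligible, the exact Gaussian-model law applies (the squared residual
correlation is Beta(1/2, (df−1)/2)). This keeps analytic single-site
p-values within Monte-Carlo error of an exact permutation test across
the whole usable range.

**Calibration.** Raw p-values are calibrated by residual permutation:
replicates permute the null residuals, the minimum-p statistic is
recomputed per replicate, and
$p = (1 + \#\{T_b \le T_{\text{obs}}\})/(B+1)$. Replicate per-$\rho$
p-values use the moment-matching approximation — applied identically
to the observed statistic, so the comparison is rank-consistent — and
$B$ defaults to 999, escalating tenfold (to at most 99,999) when the
analytic p-value falls below $10/(B+1)$. Bonferroni correction then
multiplies by the number of tests performed for that signature in the
run (recorded in the manifest); the adjusted value derives from the
calibrated p-value.

**Inflation filter.** Signature test series with genomic inflation
$\lambda = \mathrm{median}(\chi^2_{\text{obs}})/\mathrm{median}(\chi^2_1)
> 1.5$ are flagged and excluded from driver classification — too many
small p-values indicate model misfit rather than discovery.

**Per-site resolution.** For significant hotspots each site is dropped
in turn; $P_t/\min(P)$ ranks how much each site explains (ratio 1 =
least informative removal, the maximum marks the site carrying the
signal). Single-site hotspots get the trivial profile.

## Annotation and driver classification

The top site of each significant hotspot is annotated against
per-epigenome 18-state chromatin segmentations: the site is an
enhancer when the ratio of epigenomes in enhancer states (EnhG1,
EnhG2, EnhA1, EnhA2) to epigenomes in the enhancer background states
(states 1–6, 12–14) exceeds 1:2, and a TSS analogously with TssA and
TssFlnk against states 5–6, 7–15. The background sets are configurable
and deliberately typed as published despite their asymmetric overlap;
a positive state count with zero background epigenomes is an
unbounded ratio and flags true. Coding status is interval overlap with
CDS intervals; the nearest gene resolves distance ties alphabetically
with a logged note.

Enrichment of hotspot sites in coding/regulatory elements uses a
one-sided permutation test: site sets of the observed size are redrawn
uniformly over the mappable genome (mappability ≥ 0.25; draws are
position-uniform, ignoring trinucleotide composition, matching the
published design) and
$p = (1+\#\{\text{overlap} \ge \text{observed}\})/(n_{\text{perm}}+1)$
with 100,000 rounds by default. Known-driver enrichment is an
upper-tail hypergeometric test on a 21,000-gene coding background.
Both are corrected across the signature set by Benjamini–Hochberg.

A signature is **driver-associated** when both enrichments reach
q < 0.05 (the published figures star q < 0.01 and q < 0.001; 0.05 is
the package's documented default gate, configurable) and strictly more
than three events overlap Cancer Gene Census genes. A significant
hotspot of a driver-associated signature is a **putative driver** when
it (1) lies in a regulatory element, (2) lies in a coding region,
(3) has externally supplied differential-expression evidence
(expression analysis itself is out of scope; absent evidence leaves
the criterion unmet), or (4) has top-site recurrence ≥ 10. Hotspots of
other signatures are susceptible targets, never putative drivers.

## The synthetic cohort simulator

`simulate_cohort()` provides ground-truthed inputs for every stage.
Per tumor it draws an entity, a Dirichlet exposure vector (each entity
uses a rotated concentration vector, so entity is a genuine
confounder), and a genome-wide load $V_t$ from a truncated log-normal
(meanlog $\ln 2000$, sdlog 1, truncated to [50, 100,000] — the spread
of whole-genome cohorts). All $V_t$ mutations are placed on a
synthetic i.i.d.-uniform contig (default 5 Mb, inside the supported
1–10 Mb desk-scale range; larger contigs make isolated collision
sites stand out more against the thinner background and inflate the
number of eligible background regions) at positions whose pyrimidine-
strand context matches the drawn class, by sampling from precomputed
context-position pools. Planted hotspots shift the carriers' target-
signature exposure by a stated multiple of the within-entity exposure
SD — reallocating mass from the other signatures — and give every
carrier the same substitution at one context-matching site.
`simulate_null_cohort()` forces all effects to zero while keeping the
shared site, so genotypes are exactly decoupled from exposures.

What the simulator does **not** emulate: because the genome-wide load
is compressed into a short contig, the per-bp variant density is
orders of magnitude above whole-genome reality. Recurrent background
sites therefore arise by collision inside context-class pools, and
their carriers are *genuinely* exposure-biased — tumors drawing many
variants of a class are tumors with high exposure to signatures
emitting that class. These collision sites are realistic miniatures of
signature-driven recurrence without selection, and they are why
calibration checks use the planted effect-0 hotspots (whose carriers
are drawn independently of exposures) rather than every eligible
region of a null cohort. Passing tests consequently demonstrate
calibration and power of the statistical machinery, not the false-
discovery behaviour on real whole genomes, where density, chromatin-
coupled mutation rates and regional covariates differ.

Cohorts sharing a `genome_seed` share one reference contig (as real
cohorts share one genome build); the contig and its context index are
cached across simulations.

## Problem sizes and numerical choices

The shipped test and acceptance runs use the study conditions at these
sizes, stated here as the package's own choices: 300-tumor cohorts on
a 10 Mb contig; 50 seeded cohorts for the power check of a +3 SD,
30-carrier planted hotspot; six 450-hotspot null cohorts (about 2,700
planted null tests) for the inflation-factor check; 2,000 direct null
simulations for the type-I band; 100,000 residual permutations per
permutation-oracle fixture; resampling capped at 9,999 replicates
inside the large loops (the analytic p-values of planted hits are
orders of magnitude below any floor this cap imposes). Degenerate
inputs are handled explicitly: empty load vectors and all-zero
genotype matrices are errors; zero-mutation tumors get zero exposure
rows; a missing panel entry means fraction 0; dropping a site that
leaves no carriers sets its perturbed p-value to 1 with a note.

## Known limitations

* The compressed-contig density caveat above: desk-scale background
  recurrence is collision-driven and exposure-biased.
* The kernel test assumes approximately Gaussian null residuals;
  exposures are proportions, so extreme Dirichlet concentrations or
  tiny carrier counts weaken the approximation. The resampling
  calibration (which conditions on the observed residuals) is the
  guard — on the bundled simulations it holds the inflation factor
  within a few percent of 1.
* Exposure assignment by unweighted non-negative least squares is
  slightly less efficient than the maximum-likelihood estimator on
  multinomial counts; at the default five-signature sharpness and
  1,000 mutations per tumor the mean L1 recovery error sits just above
  0.05 (the shipped acceptance check reports ~0.06, and the
  information floor itself — reached by the multinomial MLE — is
  ~0.05), shrinking as loads grow.
* No copy-number-aware load adjustment, no mixed-model relatedness
  correction, no consequence-level (codon) annotation, and no de novo
  signature extraction — published or user-supplied signature matrices
  are inputs.
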
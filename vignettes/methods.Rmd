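---
title: "Methods: arm-level genotype calling and pattern classification from tumor-only SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arm-level genotype calling and pattern classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armloh)
```

## Scope and assumptions

`armloh` analyses tumor-only targeted SNP panels at chromosome-arm
resolution. The working assumptions are:

* **One clone per sample.** Every tumor cell carries the same arm-level
  genotype; the only mixture is tumor vs normal, parameterised by the
  purity $p \in (0, 1]$.
* **Integral states, total $\le 4$.** Each arm carries one of five
  states: AB (1,1), A0/0B (1,0), AA/BB (2,0), AAB/ABB (2,1), AABB (2,2).
  Higher amplifications and fractional (subclonal) states are out of
  scope; an arm whose signals fall between states is resolved to the
  nearest state and flagged low-confidence rather than given a
  fractional call.
* **Whole arms.** No sub-arm segmentation: the smallest scoreable unit is
  one of the 41 arms (autosomes + X, minus the acrocentric p-arms 13p,
  14p, 15p, 21p, 22p, which carry no scoreable unique sequence). A
  partial-arm event is encoded at arm resolution.
* **No matched normal.** Germline heterozygosity is inferred from the
  panel's population B-allele frequencies, and the coverage baseline is
  the sample's own balanced arms (self-normalization).

## Forward model

For a germline-heterozygous locus on an arm with state $(M, m)$
(major, minor allele copies) at purity $p$:

$$\mathrm{BAF}(M, m, p) = \frac{pM + (1-p)}{p(M+m) + 2(1-p)}, \qquad
  \log_2 R(M, m, p) = \log_2 \frac{p(M+m) + 2(1-p)}{2}.$$

The BAF formula is the B-major orientation; the A-major orientation is
its mirror, so the *mirrored* BAF $\max(\mathrm{BAF}, 1-\mathrm{BAF})$
equals the formula value. Useful anchor points: a hemizygous loss at
purity 0.65 sits at mirrored BAF $1/1.35 = 0.741$; cn-LOH at purity 0.8
sits at $0.90$ with $\log_2 R = 0$; a single-copy gain in a pure tumor
sits at $2/3$ with $\log_2 R = \log_2 1.5 = 0.585$.

Inversion for purity uses the two LOH states: $p = 2 - 1/m$ for a loss,
$p = 2m - 1$ for cn-LOH ($m$ = mirrored BAF). Values of $m \le 0.5$ are
uninformative (would imply non-positive purity) and raise an error.
Genome ploidy is the mean total copy number over the 23 chromosomes with
*equal* weights — not base-pair weights — because whole-chromosome
events dominate this tumor type and equal weighting is what reproduces
the conventional one-decimal reporting for near-haploid karyotypes
(e.g. 16 single-copy chromosomes + 7 diploid $\to 30/23 = 1.3$).

## The caller

### Arm summaries

Per arm: *informative* loci have depth $\ge 20$ and BAF strictly inside
$(0.05, 0.95)$ — the heterozygous-compatible band. The arm's
`median_mirrored_baf` is the median mirrored BAF of informative loci;
`het_fraction` is informative loci over non-zero-depth loci. At high
purity, full LOH pushes germline hets to BAF $\approx 0/1$, *emptying*
the band: that saturated regime is detected through the het fraction
(compared against the Hardy–Weinberg expectation from the panel's
`pop_baf`, 0.5 for the default panel), not through the mirrored BAF.
Coverage is `log2(median arm depth / balanced baseline)`.

### Two-pass self-normalization

The coverage baseline must be the diploid "height". Pass one uses the
genome-wide median depth (autosomal, non-zero loci) to compute
provisional summaries; the arms whose **allelic tier is balanced** — the
heterozygous arms — then define the final baseline, and all arms are
re-summarized against it. Anchoring to allelically balanced arms rather
than to fully neutral calls matters in heavily altered genomes: in a
near-haploid sample most loci sit on lost arms, so the genome-wide
median is the *haploid* height, and normalising to it would mirror the
genome into an apparent cn-LOH + AABB (doubled) solution. The retained
heterozygous chromosomes are the only trustworthy diploid anchor — the
same reasoning a reviewer applies when reading copy-number height
against the heterozygous chromosomes. When *no* arm is allelically
balanced the genome-wide median is kept; such genomes are genuinely
ambiguous from tumor-only data (see Limitations).

### Decision ladder and thresholds

Allelic tier: *balanced* if mirrored BAF < `imbalance_mbaf` and the het
fraction is intact; *LOH* if mirrored BAF $\ge$ `loh_mbaf` **or** the
het fraction falls below `het_deficit_fraction` × expected; *imbalance*
otherwise. Coverage tier: loss/neutral/gain at `loss_log2` / `gain_log2`.
Joint resolution:

| allelic | coverage | state | mechanism |
|---|---|---|---|
| LOH | loss | (1,0) | loss |
| LOH | neutral | (2,0) | cn_loh |
| imbalance | gain | (2,1) | gain |
| imbalance | loss | (1,0), low-confidence | loss (subclonal-like) |
| balanced | gain | (2,2) | balanced_gain |
| balanced | neutral | (1,1) | none |
| other pairs | | nearest state, low-confidence | from state |

The nearest-state fallback minimises Euclidean distance in predicted
(mirrored BAF, $\log_2 R$) space over the five states and a purity grid
$0.05, 0.06, \ldots, 1$; ties break in the fixed order AB, A0/0B,
AA/BB, AAB/ABB, AABB.

Defaults and rationale:

* `loh_mbaf = 0.75` — the conventional 0.25/0.75 markings used when LOH
  is scored on allele-frequency plots.
* `imbalance_mbaf = 0.58` — scores a single-copy gain as an imbalance at
  purity $\ge 0.4$ (mirrored BAF of (2,1) at $p = 0.4$ is 0.583).
* `gain_log2 = +0.13`, `loss_log2 = -0.15` — detect single-copy events
  at purity $\ge 0.4$ ($\log_2 R = \pm 0.26/0.32$ there) while sitting
  several standard errors above the arm-median noise of a
  37-locus arm at depth 500 under the FFPE depth model below.
* `min_informative = 8`, `het_deficit_fraction = 0.5` — an arm is a
  no-call only when both the informative-band count *and* the covered
  count fall below 8; a sample with > 50% no-call arms errors as
  uninterpretable (FFPE failure contract).

All six thresholds are overridable via the CLI's YAML `caller:` block,
and every run logs the resolved set.

A boundary note: on noise-free expected-value inputs, every state washes
out to (1,1) as purity falls — by purity 0.09 all five states are below
every threshold. Exactly at purity 0.10 the AABB state sits at
$\log_2 R = \log_2 1.1 = 0.1375$, marginally above the gain cut, so the
dilution limit is documented (and tested) at $\le 0.09$.

### Male X

Males have one germline X: no heterozygous SNPs, so the allelic tier is
undefined and X arms are called on coverage alone against a one-copy
baseline (observed $\log_2 R + 1$): gain $\to$ (2,0), loss $\to$ (0,0)
flagged low-confidence, otherwise the (1,0) baseline with mechanism
`none`. Hemizygous X arms count as altered only on a coverage-tier
change.

## Sample-level synthesis

Patterns partition interpretable samples: **1** no altered arms; **2**
loss-tier only (loss + cn_loh); **3** gain-tier only (gain +
balanced_gain); **4** both. AABB sits on the gain side — it is a
balanced *gain* — so a cn-LOH + AABB genome is Pattern 4; a sample whose
only alterations are AABB arms is Pattern 3 with a warning, a
convention for a case the pattern definitions do not address. The
altered-arm count (41 maximum) excludes no-calls; whether AABB arms
count is a switch (`count_balanced_gain`, default yes).

Massive-loss detection: a chromosome is LOH'd when $\ge 1$ scoreable arm
is LOH-tier ((1,0) or (2,0)); the flag raises at $\ge 15$ of the 22
autosomes, chosen to capture near-haploid/near-homozygous genomes
(16–21 lost chromosomes in the worked cases) while excluding ordinary
Pattern-2 samples ($\le 6$). Among LOH'd chromosomes, $\ge 60\%$
single-copy $\to$ *near-haploid*; $\ge 60\%$ copy-neutral $\to$
*near-homozygous* (the doubled descendant). Genome doubling is inferred
when (a) $\ge 10$ LOH-tier arms remain and every heterozygous arm is
AABB, or (b) $\ge 60\%$ of LOH'd chromosomes are copy-neutral.
Note the doubling *truth* flag of a simulation spec and the doubling
*inference* can legitimately disagree: a near-haploid genome observed at
single-copy coverage carries no doubling signature in this assay even if
doubling occurred — the worked near-haploid case records doubling as a
separate truth flag without reconciling the two, and the caller reports
what the data support.

The per-sample purity estimate is the median of per-LOH-arm inversions
(absent without measurable LOH arms); the ploidy estimate averages
called arm totals per chromosome, then chromosomes.

## The simulator

`simulate_sample()` emulates exactly the statistical structure the
caller assumes: Hardy–Weinberg germline genotypes from `pop_baf`
(hemizygous all-or-nothing B on the male X); per-locus depth
gamma–Poisson with mean `mean_depth` × relative coverage of the arm
state at the spec purity; B-counts binomial at the locus-level expected
BAF with random phase per locus. Germline-homozygous loci have expected
BAF exactly 0/1 regardless of tumor state.

**Depth dispersion parameterisation.** `depth_dispersion` $\delta$ is
variance inflation: $\mathrm{Var}(\text{depth}) = (1+\delta)\mu$,
implemented as negative binomial with `size` $= \mu/\delta$. The default
$\delta = 0.2$ adds 20% extra variance over Poisson — mild targeted-panel
FFPE noise. With 36–37 loci per arm at depth 500 this puts the arm
median-depth noise near 0.015 in $\log_2$, several-fold below the
coverage cuts, which is what makes whole-genome false-positive-free
calling feasible at the default thresholds.

What the simulator does *not* model — and what passing tests therefore
do not demonstrate about real data: reference/capture allele bias (the
binomial is symmetric), GC/mappability waves, locus-specific capture
efficiency, segmental
(sub-arm) events, subclonal mixtures, and contamination between samples.
Real FFPE panels show all of these; thresholds were chosen with margin,
but performance numbers from the simulation are upper bounds.

The default panel spreads 1500 loci uniformly over the 41 arms (36 or 37
per arm; the 24 extra-locus arms are a seeded draw), all at
`pop_baf = 0.5`. Real panels are designed near-uniform in exactly this
way, but the spacing within arms is not modelled — irrelevant at
whole-arm resolution.

`simulate_cohort()` draws random specs per requested pattern with
purity uniform on 0.65–0.9 (the high tumor-content regime typical of
this tumor type), whole-chromosome events, $\ge 3$ altered arms for
patterns 2–4, and male alterations restricted to autosomes. Truth tables
accompany observations and never leak into them.

## Worked patient fixtures

Six fixtures encode the worked per-patient genotype maps used
throughout testing (patterns 1/2/3/4 plus the two massive-loss cases).
Encoding decisions, where the source descriptions left room:

* Patient 49's chromosome 13 is described both as lost and as
  extrapolating to AA; it is encoded (2,0) on 13q and the ambiguity
  noted here.
* Patient 52's "part of 5q" becomes whole-5q (arm resolution).
* Patient 56's "chromosome 23" is read as X, the only non-autosome in
  the assay; its purity is 65% per the reported molecular tumor-cell
  percentage, the other fixtures default to 80%.
* Sexes of patients 52 and 56 are not on record; both are encoded
  female so X LOH is expressible allelically.

## Validation design and problem sizes

The suite validates each layer against an independent oracle: the
closed forms against $10^6$-draw Monte-Carlo read sampling (3 standard
errors); purity inversion against the forward model at $10^{-9}$; the
exact Mann–Whitney p against a brute-force pair-counting enumeration on
50 random small instances (and against the classical distribution when
tie-free); the end-to-end pipeline against the six worked patients
(25 simulation seeds each at depth 1000, requiring $\ge 24/25$ pattern
recovery) and against 200 simulated arms per state per purity level
(0.6 / 0.8 / 1.0, depth 500), requiring $\ge 99\%$ state recovery
($\ge 95\%$ for AABB, whose balanced BAF leaves only coverage
evidence). These sizes keep the full suite under a minute on one core
while leaving the stochastic checks many standard errors from their
thresholds.

One documented red check: the asymptotic Pearson chi-square p at
$n = 61$ on 2×4 tables differs from a 100{,}000-draw fixed-margins
permutation null by 0.01–0.035 at mid-range p — an $O(1/n)$ property of
the approximation (the conditional null of $X^2$ has mean
$n\,\mathrm{df}/(n-1)$, not df). The package deliberately implements
the *uncorrected* Pearson test as its contract (matching conventional
practice in the field's software), so a 3-Monte-Carlo-SE agreement with
the exact null is not achievable and the corresponding assertion is
expected to fail; the discrepancy is immaterial at the effect sizes the
test is used for (p < 0.0001 contrasts).

## Known limitations

* **Tumor-only baseline ambiguity.** A genome with *no* allelically
  balanced arms (e.g. fully doubled: all arms (2,0)/(2,2)) cannot be
  distinguished from its mirror-image solution by BAF + relative
  coverage alone; orthogonal data (matched normal, WGS purity/ploidy
  fitting) is required. The caller keeps the genome-wide median baseline
  and flags will reflect the coverage-consistent reading.
* **No subclonality.** Diluted subclonal losses surface as
  imbalance+loss and are resolved to (1,0) low-confidence.
* **Arm resolution.** Focal and partial-arm events are invisible or
  smeared into the arm median.
* **Purity below ~0.4.** Single-copy events drop below the default
  thresholds; the caller is honest about this (calls revert to
  balanced), so low-purity specimens need lowered thresholds and accept
  a false-positive trade-off.
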
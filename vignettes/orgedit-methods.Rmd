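---
title: "Quantifying and comparing organelle C-to-U RNA editing with orgedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing organelle C-to-U RNA editing with orgedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgedit)
```

## The measurement

Flowering-plant organelles edit specific cytidines to uridines in their
transcripts. Strand- and transcript-specific amplicon deep sequencing
measures, at every annotated C target, how many reads show T (edited) and
how many show C (unedited) on the transcript sense strand. The **editing
extent** at a site in a sample is

$$E = \frac{n_T}{n_T + n_C},$$

undefined when no informative read covers the site. Reads showing any
other base are tallied separately (`other`) and excluded from the
denominator: the extent is a proportion over the two informative bases
only. When counts are derived by pileup from alignments
(`pileup_counts()`), a read contributes only if it aligns to the
annotated strand (the library is strand-specific in sense orientation),
aligns an actual base at the target (deletions and reference skips carry
no evidence), and extends at least `min_base_anchor` aligned bases on
each side of the target. The anchor default of 3 nt guards against
terminal misalignment; the value is a package choice, exposed as an
argument.

## The differential-editing test

Editing extents are compared between a wild-type and a mutant genotype,
each with two biological replicates. Replicates are deliberately **not
pooled**. For every (wild-type replicate, mutant replicate) pair the
2×2 table of (edited, unedited) counts is tested with the Pearson
chi-square with one degree of freedom,

$$X^2 = \frac{N\,(e_1 u_2 - e_2 u_1)^2}{r_1 r_2 c_1 c_2},$$

and a site is called **increased** (**decreased**) only if *all four*
pairwise tests fall below the nominal threshold *and* the extent
difference satisfies $\Delta \ge 0.1$ ($\Delta \le -0.1$). Requiring the
intersection of four tests instead of one test on pooled counts is
conservative by design: a single discordant replicate vetoes the call,
so replicate-level artifacts (library composition, plant-to-plant
variation) cannot produce a call on their own.

The nominal threshold controls the family-wise error rate by Bonferroni
division: testing a family of $n$ sites at family rate
$\alpha_{fam} = 10^{-3}$ uses
$\alpha_{nom} = \alpha_{fam}/n$, which is $1.6\times10^{-6}$ (two
significant figures) for the full 612-site panel (576 mitochondrial +
36 plastid). The divisor defaults to the number of sites actually
assayed in the run rather than a hard-coded 612, so smaller panels are
tested at the matching threshold; both the family rate and an explicit
nominal override are configurable (`test_config()`).

Numerical conventions worth stating:

* the threshold comparison is strict (`p < alpha_nominal`; a p-value
  exactly at the threshold fails);
* a 2×2 table with a zero row or column margin carries no evidence of a
  difference: its statistic is defined as 0 with p = 1 rather than NaN;
* the statistic is computed closed-form in double precision and checked
  in the test suite against `stats::chisq.test()` and the regularized
  incomplete-gamma tail to $10^{-10}$ relative tolerance;
* the Yates continuity correction is off by default (the plain Pearson
  statistic) and available as a flag.

**Which Δ?** With replicates unpooled there are two natural definitions
of the extent difference: the difference of extents of replicate-summed
counts (`delta_mode = "pooled"`, the default, consistent with how such
amplicon data were analysed before replicate-intersection testing), or
the difference of per-replicate extent means (`"mean"`). Both are
implemented; with equal depths they coincide. The default is a package
choice, not a claim about any particular study's convention.

**Minimum depth.** A chi-square on a handful of reads is meaningless. A
site with fewer than `min_depth = 100` informative reads in any tested
sample is flagged `not_assayed`, excluded from all category counts and
removed from the Bonferroni family for that run. The floor of 100 is a
package choice on the same grounds.

Two mutant alleles of the same factor are analysed independently and
then intersected (`intersect_classifications()`): sites called in the
same direction in both are the `common_increased` / `common_decreased`
sets; single-mutant and discordant calls are reported separately.

## Transgenic complementation

A transgenic line (a single plant expressing the factor in a mutant
background) is tested per site against *each* replicate of its
background mutant; all pairwise tests must pass at the same nominal
threshold, and $|\Delta_T| \ge 0.1$ where
$\Delta_T = E_T - E_M$ against pooled mutant counts. The requirement
that every transgenic-vs-replicate comparison passes mirrors the
replicate-intersection logic of the mutant test; a configurable
any-comparison reading would be less conservative, and the package
adopts the conservative one.

A site **responded** if it is significant *and* moves in the expected
direction: sites increased in the mutant should decrease in the
transgenic, and vice versa (`expected_direction()`). The magnitude of
rescue is summarised by the **complementation effect**

$$CE = \frac{E_T - E_M}{E_{WT} - E_M},$$

with $E_{WT}$ from pooled wild-type counts (consistent with the pooled
delta mode): 1 is exact restoration of the wild-type level, 0 no
response, and $CE > 1$ (strictly) a transgressive overshoot, the
expected signature of strong-promoter overexpression. CE is undefined at
sites where $E_{WT} = E_M$ — there is no gap to close. CE is invariant
under adding a constant to all three extents, and any $0 < CE < 2$
implies the transgenic narrowed the gap to wild-type.

With two transgenic lines per background, mutant-affected sites are
partitioned into rescued in **both**, **only one**, or **neither** line,
with percentages rounded half away from zero; the inclusive
(at-least-one) percentage is also reported. Sites *invariant* in the
mutant can still change in the transgenics under overexpression;
`invariant_site_response()` counts them by direction and by one-vs-both
stratum.

## Splicing efficiency

For an intron with annotated bounds, splicing efficiency in a sample is

$$SE = \frac{n_{spliced}}{n_{spliced} + n_{unspliced}},$$

where `junction_counts()` defines: *spliced* = alignments with exactly
one reference skip whose span equals the annotated intron (exact match
by default; a per-end tolerance in nt is configurable) and at least
`anchor` aligned bases on each flanking exon; *unspliced* = ungapped
alignments covering an exon–intron boundary with at least `anchor`
bases on both sides, summed over the two boundaries. The anchor default
of 6 nt and the both-boundaries rule are documented package choices —
junction-counting tools differ in these internals, and fixing them
explicitly is what makes the number reproducible. The same ratio
applies unchanged to relative expression levels of spliced- and
unspliced-specific amplicons from qRT-PCR, so `splicing_efficiency()`
accepts non-integer inputs. Per-genotype summaries report the Welch
(unequal-variance) t statistic between genotypes as a display statistic
only — with two biological replicates per genotype it has no serious
inferential content, and it is labelled accordingly.

## Cross-mutant dependence

To ask whether the sites affected in one mutant are preferentially
affected in another, sites are cross-classified
({increased, decreased, invariant} × the same, or a 2×2
affected/invariant collapse) and tested with the Pearson chi-square of
independence; standardized residuals $(O-E)/\sqrt{E}$ localise which
cell drives a significant statistic. An excess in the (increased in A,
decreased in B) cell is the signature expected if factor A normally
sequesters factor B away from shared target sites. Zero-margin rows or
columns are dropped with a warning. Printed percentage roll-ups
(`round_percent()`) round half away from zero, matching the convention
of printed study summaries (`round()` in R rounds half to even and
would disagree at exact halves).

## The synthetic-data generator

The generator exists so that every stage is testable with no external
data, and its defaults are the study conditions the package emulates:

* **612 sites** (576 mitochondrial + 36 plastid) distributed over 24
  transcripts, with per-transcript strand and field-style identifiers
  (`nad7_C789`);
* **effect structure**: 14% of mitochondrial sites increased and 3%
  decreased in the mutant, all plastid sites invariant (the emulated
  factor is mitochondrial); class counts are realised as
  `round(frac × n)` half away from zero; |Δ| is drawn uniformly, with
  the lower bound of the delta range (default 0.1) a guaranteed minimum
  — base extents are resampled (boundedly) so that clipping to [0, 1]
  can never shrink a planted effect below it;
* **two mutant alleles share one truth table**, as two knockouts of the
  same gene would; transgenic truth is
  $E_T = E_M + r\,(E_{WT} - E_M)$ with restore fraction $r$ ($r=1$
  full rescue, $r>1$ transgressive), plus an optional additive shift on
  mutant-invariant sites to emulate the off-target response of
  overexpression;
* **counts** are Binomial(depth, true extent), drawn independently per
  (site, sample) — exactly the sampling model the 2×2 chi-square
  assumes. Depth is a free parameter (per-site depth distributions of
  real amplicon pools are not modelled); defaults used in the analysis
  scripts are depth 2000 for classification and 1000 for the
  null-calibration batches. A beta-binomial dispersion parameter and a
  base-calling error rate (reads diverted into `other`) are available
  for robustness work, both off by default;
* **alignments**: toy per-transcript references carry C (sense) at every
  annotated target; site-covering reads show T with probability equal
  to the true extent — at *every* target they cover, since amplicon
  reads span neighbouring sites — and are emitted on the annotated
  strand (reverse-strand flag on '-' transcripts). Junction reads over
  the intron are gapped with probability equal to the true splicing
  efficiency, with the gap matching the intron exactly, and ungapped
  across a random boundary otherwise. Output is plain SAM with headers;
  a truth sidecar TSV accompanies every run.

All generator functions are deterministic given their seed, and restore
the caller's RNG state.

**What passing on synthetic data does and does not show.** The
generator emulates the *count structure* of amplicon editing data:
binomial sampling at configurable depth, the effect-class layout, exact
splice junctions, strand-specific ungapped site reads. It deliberately
does not emulate PCR amplification bias, sonication fragment-size
effects, base-quality errors (beyond a flat error rate), overdispersion
between biological replicates (beyond the optional beta-binomial), or
editing-site discovery — the site catalog is always an input. Results
on synthetic data therefore validate the statistical machinery and the
counting rules, not the upstream wet-lab pipeline; with real data the
conservative four-test intersection is precisely the guard against the
replicate-level variation the generator omits by default.

## Calibration at the study design points

The test suite and `scripts/acceptance.R` exercise the pipeline at the
emulated design: 612 sites, 2+2 replicates. Null calibration uses 200
all-invariant batches at depth 1000 and requires no false call in at
least 99% of batches — the four-test intersection at
$\alpha_{nom} = 1.6\times10^{-6}$ with the Δ floor makes false calls
vanishingly rare (the intersection p-value under the null is far below
$\alpha_{nom}$ itself). Recovery uses planted effects with
$|\Delta| \in [0.15, 0.4]$ at depth 2000 and requires at least 90% of
non-invariant sites recovered with at most 1% misdirection; at these
depths the per-pair noncentral statistic is large and recovery is
essentially complete. Splicing recovery uses 10 000 junction reads per
sample: exact at the degenerate efficiencies 0 and 1, within three
binomial standard errors at 0.5. These problem sizes are the package's
chosen design points for its own validation.

## Known limitations

* The classifier assumes exactly the binomial sampling model; with
  strong replicate overdispersion the nominal threshold is
  anti-conservative per pair (the four-test intersection mitigates but
  does not remove this). The beta-binomial generator option exists to
  probe that regime.
* Single-sample transgenic lines have no replicate structure of their
  own; their test inherits all replication from the mutant side.
* `junction_counts()` uses one documented boundary rule; other
  junction-counting tools may count differently, so absolute unspliced
  counts (not efficiencies at matched rules) are not directly
  comparable across tools.
* The pipeline classifies a fixed site catalog; it does not discover
  sites, call variants, or model trans-splicing.
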
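---
title: "Methods: event extraction, PSI, permutation testing and the SSS calculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event extraction, PSI, permutation testing and the SSS calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexsplice)
```

# Scope and model

`sexsplice` analyses *local* alternative-splicing events: places where two
transcripts of the same gene disagree in a bounded region while agreeing on
its flanks. Seven classes are distinguished — skipped exon (SE), mutually
exclusive exons (MXE), alternative 5′/3′ splice site (A5/A3), retained
intron (RI), and alternative first/last exon (AF/AL). Every event carries
two transcript sets: the *inclusion* form and the *exclusion* form, and the
quantitative unit throughout is the percent spliced in,

$$\mathrm{PSI} = \frac{\sum_{t \in \text{inclusion}} a_t}{\sum_{t \in \text{inclusion} \cup \text{exclusion}} a_t},$$

with $a_t$ a transcript abundance (TPM). In read-count terms this is
IR/(IR+ER) with IR the reads supporting inclusion and ER the reads
supporting exclusion. ΔPSI between two sample groups is the difference of
group means of per-replicate PSI, positive when inclusion is higher in the
first-named group.

All internal coordinates are 0-based half-open; GTF input is converted on
read (start − 1, end) and back on write, BED-family formats are kept
verbatim. A single convention everywhere avoids off-by-one drift between
the annotation, peak and coverage paths.

# Event extraction

Events are generated per gene by pairwise comparison of transcript exon
chains and deduplicated by (class, defining coordinates). A junction is the
pair (end of upstream exon, start of downstream exon). The class rules, in
transcription orientation:

* **SE** — one chain walks junctions $(e_1,s_2),(e_2,s_3)$ around a
  cassette exon $(s_2,e_2)$; the other bridges $(e_1,s_3)$.
* **MXE** — two internal, non-overlapping exons between shared flanking
  boundaries $e_1$ and $s_3$, with *strict* mutual exclusivity: if any
  transcript of the gene carries both exons, the pair is not an MXE event.
* **A5/A3** — two junctions share one boundary and differ in the other,
  *and* the two variable-side exons share their remaining boundary (they
  are the same exon with two donor or acceptor choices). The inclusion form
  is the longer-exon form, i.e. the junction with the shorter intron.
* **AF/AL** — the variable-side exons are the transcripts' terminal (first
  or last) exons and are non-overlapping, splicing into a shared boundary.
  Inclusion is the distal form: the 5′-most first exon (AF) or the 3′-most
  last exon (AL).
* **RI** — a single exon $(s_1,e_2)$ of one transcript exactly spans two
  exons $(s_1,e_1),(s_2,e_2)$ of another; inclusion is the intron-retaining
  form.

The A5/A3 shared-boundary requirement is what keeps the rule set coherent:
without it, every cassette exon would *also* produce an alternative-site
event from the junction pair $(e_1,s_2)$ versus $(e_1,s_3)$, and terminal
variable exons would be double-counted against AF/AL. A junction pair that
satisfies neither the shared-boundary nor the terminal-exon condition is a
complex difference and yields no event. One useful symmetry falls out of
these definitions: reflecting all coordinates through a fixed point while
*keeping* the strand label swaps AF↔AL and A5↔A3 and preserves SE/MXE/RI;
reflecting *and* flipping the strand is an isomorphism of
transcription-oriented structure and preserves every class. Both statements
are asserted in the test suite over random genes, alongside equivalence
with an independent brute-force enumerator.

Supporting transcripts of each form are *all* transcripts of the gene whose
chain carries the form's defining signature, not only the generating pair;
events identical under (class, coordinates) are merged. The denominator of
PSI is the union of the two forms' supporting sets only — transcripts
matching neither form do not dilute the ratio (ioe semantics).

# PSI and the expression filter

PSI is missing (`NA`) when the event's denominator abundance is below
$10^{-12}$: an unexpressed event has no defined inclusion ratio, and
missingness is propagated, never imputed. Two invariants pin the
implementation down: swapping the inclusion/exclusion roles complements PSI
(`1 − PSI`), and multiplying all abundances of a sample by any $c > 0$
leaves PSI unchanged.

The low-expression filter drops an event when the mean of its denominator
TPM over the samples under comparison is ≤ 3 (configurable). The cutoff
reflects where the filtered fraction typically plateaus when the threshold
is swept over 1–10 TPM. Filtering operates on the *event denominator*, not
whole-gene TPM, because the denominator is the quantity whose shot noise
corrupts the ratio; a per-gene variant would be defensible and callers can
emulate it by passing gene-level events. The filter direction is exclusion
of low expression — i.e. events are *kept* above the threshold — which is
the only direction under which a plateau rationale is meaningful.

# Differential splicing by label permutation

Significance comes from a replicate-label permutation test on
$T = |\bar{x}_A - \bar{x}_B|$. When $\binom{n_A+n_B}{n_A} \le$ `max_exact`
(default 20 000) all distinct reassignments are enumerated and

$$p = \frac{\#\{T^{*} \ge T_{\mathrm{obs}} - 10^{-12}\}}{\#\text{reassignments}},$$

which includes the observed assignment, so $p > 0$ always. Otherwise
`max_exact` reassignments are sampled and the add-one estimator
$(b+1)/(m+1)$ is used. The $10^{-12}$ tie tolerance makes floating-point
ties deterministic across platforms. Events with fewer than two non-missing
replicates in a group are excluded from testing and reported in a
skipped-events list rather than silently lost.

This test replaces the expression-conditioned empirical null used by
transcript-quantification pipelines with a self-contained, exactly
enumerable procedure: it is oracle-checkable (the suite verifies it against
full subset enumeration for all group sizes up to $n_A+n_B = 8$) and
asymptotically valid under exchangeability.

**Discreteness at small replicate numbers.** With four replicates per
group there are $\binom{8}{4} = 70$ reassignments, and they pair up — a
subset and its complement give the same $T$ — so the attainable p-values
are multiples of $2/70$. At $\alpha = 0.05$ the only attainable rejection
is $p = 2/70 \approx 0.0286$, hence the null rejection rate of the exact
test is *exactly* $1/35$, not $0.05$: the test is conservative, as every
discrete exact test is, and no estimator choice within this design can
yield a rejection rate of $0.05$ at 4v4. The test suite asserts the rate
against its true value $1/35$ (and validity, rate ≤ α); a nominal-rate
assertion centred on 0.05 would fail by construction and one such check is
deliberately retained, failing, in the acceptance tests as a record of this
property.

Significance calls combine $p < \alpha$ (default 0.05, raw — no
multiple-testing correction across events, matching the screening use) with
an effect floor $|\Delta\mathrm{PSI}| \ge$ `dpsi_min`. The floor defaults
to 0 for embryo-style screens; 0.2 is the conventional volcano-plot setting
for cell-line comparisons. Whether an effect floor should also apply to the
embryo-style screens is genuinely open; both are exposed.

# The SSS calculus

At one time point, three comparisons feed the classifier: $S$ (female vs
male controls), $D_F$ and $D_M$ (depleted vs control within each sex).
"Sex-specific" for a condition-dependent event is defined purely by set
difference — responsive in one sex and not the other — rather than by a
formal interaction test:

* female sex-specific $= D_F \setminus D_M$, male symmetric;
* non-sex-specific $= D_F \cap D_M$;
* *known* SSS $=$ sex-specific $\cap\, S$; *new* SSS $=$ sex-specific
  $\setminus S$.

The per-sex partition (known ∪ new ∪ non = that sex's condition-dependent
set, pairwise disjoint) is asserted on every call. An interaction test
would trade faithfulness to this set-theoretic definition for power and is
deliberately not the default. Events are the classification unit;
gene-level summaries deduplicate afterwards (a gene is SSS if any of its
events is). Direction of change (inclusion vs exclusion) is carried through
but does not affect membership.

Enrichment summaries use a two-sided Fisher exact test on the 2×2 table of
membership in $S$ versus membership in $D$ over the tested background, and
generic gene-set over-representation uses the one-sided hypergeometric
upper tail with Benjamini–Hochberg correction across sets. Backgrounds are
always explicit inputs — the package bundles no gene-set databases, and a
query gene outside the background is an error rather than a silent drop.

# Chromatin integration

Peaks are assigned to genes by interval overlap with the gene span (a peak
overlapping several genes counts for each). The peak reference point is the
narrowPeak summit when present, else the interval midpoint — summits are
the sharpest localisation the format offers. Distances to the nearest
splice-junction boundary are unsigned and histogrammed in 200 bp bins by
default. An optional filter restricts to peaks whose reference point falls
in an intron of the assigned gene.

Metagene profiles use scale-regions semantics: fixed-size flank bins
(default 50 bp over ±500 bp), the gene body divided into `n_body_bins`
(default 100) equal fractional-width bins, each valued by the exact mean of
the piecewise-constant coverage over its bases, minus-strand genes reversed
so profiles run TSS→TES. Flank sizes must be multiples of the flank bin
size (errored, not silently rounded). Bin values are invariant to splitting
coverage intervals into equal-valued pieces; genes shorter than the bin
count are dropped and reported; chromosomes absent from the track
contribute zeros with a warning. A reference-point variant can be emulated
with zero-length flanks around a degenerate body and is otherwise out of
scope.

The resampled baseline answers "what would an average gene look like":
sample `n` genes uniformly without replacement from a user-supplied active
pool, compute the metagene mean profile, repeat `reps` times (default 500)
and average element-wise. With `reps = 1` and `n` equal to the pool it
reduces exactly to the pool mean, and as `reps` grows it converges to the
pool mean with Monte-Carlo error shrinking as $1/\sqrt{\text{reps}}$ — both
properties are asserted. Activity of the pool is the caller's definition
(e.g. genes above the expression filter); it is never derived from the
occupancy data being profiled.

Overlapping bedGraph intervals are flattened by position-wise *summation*,
not last-wins, which conserves total signal mass
$\sum \text{value} \times \text{length}$ and makes fixtures easy to
construct additively.

# The synthetic-data module

The generator emulates the study design the package targets: two sexes ×
time points × control/depleted × 4 replicates, with planted events of all
seven classes. Each simulated gene is a two-transcript archetype of one
class with kilobase-scale exons and introns; genes are spaced 10 kb apart
on one chromosome. Replicate PSI noise is logit-normal — symmetric on the
logit scale, closed-seed reproducible, with `noise_sd_logit` in logit units
(default 0.3) — and the knockdown effect is a shift of the true PSI
(default 0.3 → 0.8, i.e. |ΔPSI| = 0.5) in the depleted condition of the
designated sex(es). The four archetypes map one-to-one onto the classifier
categories: *known* (sex-different in controls, responsive in one sex),
*new* (sex-equal in controls, responsive in one sex), *non* (responsive in
both), *null* (no effect). Gene expression defaults to 30 TPM total,
comfortably above the 3-TPM filter, so filtering and classification can be
tested independently.

What the generator does **not** emulate: read-level sampling noise and
mapping ambiguity (abundances are exact given the drawn PSI), multi-isoform
genes with more than two forms per event, correlated events within a gene,
library-size or batch effects, and maternal transcript decay over time.
Passing tests therefore demonstrate correctness of the calculus and
estimators under the stated noise model, not robustness to quantification
artefacts — those enter upstream of this package.

Peak simulation places one 200 bp peak per gene per requested offset, with
the summit at a seeded random junction ± offset; placements whose realized
nearest-junction distance equals the intention are preferred, and the truth
table records the realized value so tests never assert a fiction. Coverage
shapes are `constant` (value 1 over gene spans), `tss_peak` (stepped
triangular bump at the TSS) and `body_uniform` (one uniform value per
gene).

# Numerical choices and problem sizes

* PSI denominator positivity: $10^{-12}$; permutation tie tolerance:
  $10^{-12}$; ΔPSI is reproducible to the same tolerance.
* Chi-squared tests are Pearson without continuity correction, dropping
  classes with zero total across both conditions (df adjusts); an
  all-zero table is an error, a class absent from a 2×2 comparison yields
  p = 1 with a warning.
* Event ids render coordinates 1-based for human readability and are
  parsed back exactly; catalogs, PSI matrices and simulations round-trip
  byte-identically, and all generators are bit-reproducible under a fixed
  seed.
* Test and acceptance problem sizes were chosen for statistical head-room:
  oracle equivalence runs on 500 random genes (≤ 4 transcripts, ≤ 6
  exons); null calibration on 2000 events (4v4); category recovery on 300
  events per archetype, where the expected per-category accuracy under the
  default conditions is 0.94–1.00 (bounded by the $1/35$ false-positive
  rate of the exact test), keeping the ≥ 90 % assertion far from its
  boundary; baseline convergence on a 50-gene pool at 2000 repetitions.

# Limitations

The package quantifies and classifies; it does not align reads, call
peaks, or estimate transcript abundances. The set-difference definition of
sex-specificity inherits threshold effects: an event marginally significant
in one sex and marginally not in the other is called sex-specific without
evidence of interaction. Exact permutation p-values at small replicate
numbers are coarse (35 attainable levels at 4v4), which bounds achievable
sensitivity regardless of effect size. MXE strictness means genes with a
minor isoform carrying both alternative exons lose the event entirely
rather than reporting a diluted one.
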
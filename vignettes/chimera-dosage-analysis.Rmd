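---
title: "Dosage-based detection and layer assignment of periclinal chimeras"
author: "chimeradose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-based detection and layer assignment of periclinal chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeradose)
```

## The forward model

Shoot apical meristems maintain clonally separate cell layers: L1 builds
the epidermis, L2 and L3 the inner tissues. A mutation fixed in one layer's
stem cells spreads through that layer and nowhere else, producing a
periclinal chimera. Bulk DNA from an organ therefore mixes genomes in
proportion to the layers' cell fractions.

`chimeradose` works on *normalized dosage*: per-bin read counts of a mutant
divided by a control library bin-by-bin, scaled so unaffected regions sit
at 1. Against a haplotype-resolved assembly, the control carries one copy
of each scaffold, so a single-haplotype event confined to layer set $S$
has expected dosage

$$d \;=\; 1 + s\,c\,f_S,$$

with $s=-1$ for deletions and $+1$ for insertions, $c$ the copies changed
per affected cell (default 1), and $f_S$ the summed cell fraction of $S$ in
the sampled tissue (`expected_dosage()`). Two properties anchor the test
suite: a deletion and an insertion of the same layer set sum to dosage 2,
and deletion dosage decreases strictly in $f_S$.

L2 and L3 are merged into a single `L23` compartment: leaf read-depth
cannot separate them, and adventitious roots — which regenerate from L3
alone — behave as pure `L23` for every quantity computed here. The
`layer_model()` for roots carries an `l3_only` flag to record that its
inner compartment is specifically L3-derived.

**Leaf L1 fraction.** The default `l1 = 0.30` is taken from the observed
band centers of layer-specific deletions in mint leaf tissue (~0.7 for
L1-only, ~0.3 for L2/3-only). The fraction is a tunable parameter because
it is species-specific (potato leaves run closer to 0.2/0.8). Whether the
band centers reflect cell number or per-cell DNA content is not
resolvable from read depth; the model treats them as read fractions, which
is the quantity the data actually constrain.

## Dosage bands and classification

Observed mean dosages cluster in bands around the model values, separated
by gaps. `dosage_bands()` places centers at 0 / `l1` / `1 - l1` for
deletions (mirrored for insertions) with half-width 0.15. With defaults,
deletions classify as: $d<0.15$ all layers, $0.15\le d<0.5$ L2/3,
$0.5\le d\le0.85$ L1, and $d>0.85$ no-call; insertions as $(1.15,1.45]$
L1, $(1.45,1.85]$ L23, $>1.85$ all. Dosages in the gaps are reported as
`no-call` rather than force-assigned: the empirical dosage distribution is
multimodal with genuinely empty space between bands, and a value in a gap
usually signals poor normalization or a sectorial (non-periclinal) sector.
Population summaries carry these calls as an explicit *unclassified*
stratum so totals remain honest.

Root libraries corroborate leaf assignments (`infer_layer_leaf_root()`):
an L1 deletion should vanish in roots (dosage $\ge 0.85$), an L2/3
deletion should be complete ($\le 0.15$). Root evidence sets a concordance
flag but never overrides the leaf-derived layer — root sequencing is
treated as confirmation, not primary evidence, and a discordant pair is
worth a human look rather than a silent reassignment.

An individual whose calls are all full-dosage events (`all`) is
*homogenized*: a layer invasion has propagated one layer's genome through
the plant. Any layer-specific call makes the individual chimeric.

## Normalization

`normalize_to_control()` computes per-bin ratios and scales by the
genome-wide **median** ratio. A mean-based library-size factor would be
biased by the megabase deletions the samples are selected to contain; with
a few percent of the genome affected, median and mean agree to well under
1%, but the median stays correct as the affected fraction grows. Bins
whose control count falls below 25% of the control median are masked:
their ratios are dominated by the denominator and carry no usable dosage
signal. Masked bins are *transparent* downstream — they neither break nor
extend runs. The order of operations (per-bin ratio first, then one global
scale factor) is fixed and documented here; the median of unmasked dosages
is exactly 1 by construction, which the suite asserts.

The ratio of two counts is a slightly biased estimator of the dosage:
$E[X/Y] \approx d\,(1 + 1/\mu_Y)$, i.e. about +0.1% at depth 1,000 and
+0.5% at depth 200. This is far inside the band half-widths and is left
uncorrected; it is visible as a ~0.005 upward shift when measuring a 0.7
band at depth 1,000.

## Segmentation

`detect_indels()` implements run-seeding with flank extension
(`detection_params()` defaults in parentheses):

1. **Seeding** — maximal runs of at least `min_size` (5) consecutive
   unmasked bins at dosage $\le$ `del_cut` (0.80) or $\ge$ `ins_cut`
   (1.15). `seed_runs()` is checked against a brute-force enumeration.
2. **Extension** — each seed grows outward in look-ahead windows of
   `extend_win` (10) bins; a window is absorbed when at least
   `extend_frac` (0.6) of its bins pass the relaxed cut `post_core_cut`
   (0.85; insertions mirror at $2-0.85=1.15$). A failing window is still
   absorbed when the `post_run_bins` (10) bins beyond it pass at the same
   rate (re-qualification). A flank stops when it fails to re-qualify or
   when the cumulative count of absorbed non-passing bins exceeds `pen`
   (25); the budget is tracked per flank.
3. **Trimming** — after extension stops, the stopping window is considered
   provisionally and the boundary is set at the outermost bin that (i)
   passes the relaxed cut together with its inward neighbor and (ii)
   keeps at least `extend_frac` of the bins between the seed edge and
   itself passing. Condition (i) stops an isolated noisy bin from setting
   a boundary; condition (ii) stops a distant noisy pair from dragging the
   boundary across a non-passing stretch. Both failure modes occur at
   realistic depths (a baseline bin dips below 0.85 about 2–3% of the time
   at depth 200) and each costs several bins of boundary error when
   unguarded.
4. **Merging** — same-type calls on one scaffold separated by at most
   `gap_bins` (30) unmasked bins merge, and the mean dosage is recomputed
   over the merged interval. Where a deletion and an insertion call
   overlap (possible only through gap bridging), the call with the larger
   $|d-1|$ wins and the other is truncated off the overlap: opposite-sign
   overlaps are artifacts of bridging, and the stronger departure from
   baseline is the better-supported call.
5. Calls shorter than `min_size` bins after trimming are dropped.

Boundaries are reported at bin resolution (the data are low-pass; sub-bin
breakpoints are out of scope). Manual boundary curation is replaced by the
deterministic trim rule; `write_calls()` emits a review TSV for optional
hand edits. The original tool's exact semantics for `pen` and
`post_run_bins` are not published; the semantics above are fixed,
documented, and configurable, and the package's guarantees rest on
synthetic-truth recovery and on clean printed examples, which are robust
to these choices.

## The synthetic population generator

The simulator is first-class, tested code: it defines the statistical
conditions under which every guarantee is stated.

* **Event counts** are zero-inflated Poisson. `lambda` is the target mean
  indels per individual per dose (15 Gy: 2.62, 30: 4.71, 45: 5.66,
  60: 7.00 — the observed per-sample rates), and the Poisson component
  uses rate $\lambda/(1-\pi_0)$ so the population mean equals `lambda`
  exactly. The zero-inflation mass $\pi_0 = 0.145$ is calibrated so the
  indel-free fraction at 45 Gy is ~0.15; a plain Poisson at rate 5.66
  would leave essentially no indel-free individuals
  ($P(0) \approx 0.3\%$), contradicting the ~15% observed.
* **Type and layer biases**: deletions with probability 0.963; among
  non-homogenized events, all-layer with probability 0.036, otherwise L1
  with probability 0.622 (an L1:L2/3 ratio of ~1.65). A whole individual
  is homogenized with probability 11/261, in which case all its events
  are all-layer.
* **Sizes** are lognormal with configurable mean 6.4 Mb and log-sd 0.8
  (only per-dose mean sizes are observed; the log-sd is a modeling choice
  giving a realistic right-skewed spread), truncated to the scaffold and
  floored at 5 bins.
* **Placement**: with probability 0.6 an event anchors at a scaffold end
  (terminal-arm deletions predominate in irradiated material), otherwise
  uniform. Events of the same layer set may not overlap on a scaffold;
  different layer sets may, which is how compound full-loss regions arise.
* **Rendering**: bin counts are Poisson with mean
  `depth × dosage × bin_fill` (negative binomial when an overdispersion
  parameter is set); truth dosage uses the same forward model as
  `expected_dosage()`, with partial bins attenuated by overlap fraction,
  so there is no stochastic gap between the simulator and the model it
  tests.
* **Reproducibility**: one global seed; each individual draws from a
  substream derived deterministically from (seed, index), so any
  individual can be regenerated alone.

What the generator does *not* emulate: GC and mappability bias, repeat
and centromere artifacts, duplicate reads, or read-level error. Passing
recovery tests therefore demonstrates correctness of the statistical
machinery under the stated noise model, not robustness to every artifact
of real libraries (a real control normalization absorbs much, not all, of
those shared biases).

**Problem sizes.** The demonstration layout (`demo_layout()`) is a
deterministic hexaploid-like set of 72 scaffolds of 10–30 Mb (~1.4 Gb,
~14,400 bins at 100 kb), and the recovery suites run 25–50 individuals at
depth 200. These desk-scale sizes keep the full suite under a minute
while leaving per-bin noise at realistic low-pass levels; a full-scale
scaffold table loads via `layout_from_tsv()`.

## Reconstructing profiles from printed indel tables

`profile_from_indel_table()` rebuilds a per-bin profile from published
(scaffold, start, end, mean dosage) rows: a bin takes a row's dosage when
its **midpoint** falls inside the row's interval; all other bins sit at
baseline 1. The midpoint rule resolves off-by-one-base end coordinates in
printed tables without spilling events into an extra bin. Gaussian jitter
(`baseline_noise_sd`) applies to baseline bins only: event bins carry a
printed *measured mean*, and re-noising them would double-count noise —
in particular, a printed mean sitting exactly on the 0.80 seeding cut
would otherwise be re-detected only by luck. The scaffold lengths used for
the packaged reconstruction (`fixture_layout()`) are synthetic: true
lengths are not printed, so indels with non-bin-aligned end coordinates
are taken to run to the scaffold end, and other scaffolds get a 3 Mb
margin.

Two discrepancies in the packaged tables are shipped verbatim rather than
silently corrected: the P028 rows sum to 18.9 Mb over four entries while
the accompanying text says three indels and 18.5 Mb, and the printed
menthol reduction (42% to 2.6%) is described as 12-fold although the ratio
is 16.2. P028- and menthol-fold-based checks are therefore excluded from
the package's verification targets; `fold_changes()` reports the computed
ratio.

## Population and chemotype summaries

Interval algebra (union coverage in `layer_summary()`, cross-individual
intersection in `shared_deleted_regions()`, gene overlap in
`genes_in_intervals()`) is delegated to GenomicRanges and cross-checked
against per-bin brute-force oracles in the suite. Border density counts
each call boundary that is not a scaffold end, so whole-scaffold
aneuploidies contribute no border and terminal-arm events contribute one;
a 1 Mb window is the default granularity. Report-table rounding follows
the conventions of the source tables (two decimals for rates and ratios,
one for percentages); all functions return unrounded values.

Oil-profile fold changes are reported as larger-over-smaller with a
direction flag, so 10-fold losses and gains print symmetrically; zero
abundances flag the ratio undefined instead of dividing. Pearson
correlations use `stats::cor.test` per pair (t-distribution p-values,
n−2 df) over either margin of the long table: samples across shared
compounds, or compounds across samples.

## Known limitations

* No GC/mappability correction and no duplicate handling; upstream
  concerns.
* Boundaries are bin-resolution by design; at depth 200, ~93% of
  simulated boundaries land within one bin, and errors concentrate where
  an event boundary falls mid-bin.
* The layer model assumes exactly two compartments with stable fractions
  across samples; mericlinal/sectorial sectors (unstable fractions) are
  out of scope, as is any model of layer-invasion dynamics or germline
  transmission.
* Insertions are modeled as +1 copy events; the data do not distinguish
  tandem duplication from insertional translocation.
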
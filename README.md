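# chimeradose

Read-depth dosage analysis of periclinal chimeras in polyploid mutant
populations.

## The problem

Irradiating buds of a clonally propagated crop (the motivating system is
hexaploid peppermint, sequenced against a haplotype-resolved assembly of
~100 scaffolds) induces megabase-scale deletions and insertions. Because a
shoot apical meristem is organized in clonally separate cell layers — L1
(epidermis, including the glandular trichomes that make essential oil) and
the inner L2/L3 — a mutation arising in one stem cell stays confined to its
layer, and most surviving mutants are *periclinal chimeras*: genetically
different genomes stacked in one plant.

Bulk DNA from a leaf is a mixture of cells from all layers, so a
layer-specific event shows up at a fractional copy number. With per-bin
read counts normalized to an unirradiated control so that unaffected
regions sit at dosage 1, a single-haplotype event confined to layer set *S*
has expected dosage

```
d = 1 ± f_S
```

where `f_S` is the cell fraction of *S* in the sampled tissue and the sign
follows the event type. In leaf tissue with an L1 fraction of 0.3 this
puts deletions at characteristic bands near 0.7 (L1-only), 0.3 (L2/3-only)
and 0 (all layers), and insertions at the mirror bands 1.3 / 1.7 / 2.
Adventitious roots regenerate from L3 alone, so a root library resolves the
assignment: an L1 deletion vanishes in roots (dosage ~1) while an L2/3
deletion becomes complete (dosage ~0).

The package implements the full pipeline around that model:

* **Simulation** (`sim_config`, `simulate_population`, `render_bin_counts`)
  of irradiated populations with dose-dependent zero-inflated event counts,
  deletion and L1 biases, homogenized individuals, lognormal sizes,
  terminal-arm placement, and Poisson or negative-binomial bin counts —
  with ground truth for every downstream stage.
* **Coverage binning and normalization** (`bin_counts_from_alignments`,
  `normalize_to_control`): 100-kb bin counts from coordinate-sorted
  BAM/SAM (mapping quality >= 40), median-scaled control normalization with
  masking of uninformative bins.
* **Segmentation** (`detect_indels`): run-seeding at dosage cuts 0.80/1.15,
  look-ahead flank extension under a relaxed cut, gap bridging, and
  boundary trimming, at bin resolution.
* **Layer classification** (`classify_call`, `infer_layer_leaf_root`,
  `classify_individual`): dosage-band assignment, leaf/root concordance,
  chimeric vs homogenized status, compound full-loss regions.
* **Population summaries** (`dose_response_table`, `layer_summary`,
  `border_density`, `shared_deleted_regions`, `genes_in_intervals`).
* **Chemotype summaries** (`fold_changes`, `correlation_matrix`) for
  essential-oil composition tables.

## Worked example

Simulate one 45 Gy individual on the desk-scale hexaploid layout, render
leaf sequencing at depth 200, normalize against a rendered control, and
call and classify indels:

```r
library(chimeradose)

layout <- demo_layout()                      # 72 scaffolds, ~1.4 Gb
cfg    <- sim_config(dose = 45, n_individuals = 3, depth = 200)
pop    <- simulate_population(cfg, layout, seed = 7)
ev     <- pop$events[pop$events$individual == "sim002", ]

leaf  <- render_bin_counts(ev, layout, layer_model("leaf"), depth = 200, seed = 1)
ctrl  <- render_bin_counts(NULL, layout, layer_model("leaf"), depth = 200, seed = 2)
prof  <- normalize_to_control(leaf, ctrl)
calls <- classify_calls(detect_indels(prof))
print(calls, digits = 3)
#>   scaffold    start      end     type n_bins mean_dosage size_mb layer
#> 1  Chr02_E   100001  1700000 deletion     16       0.727     1.6    L1
#> 2  Chr03_F 10800001 13100000 deletion     23       0.332     2.3   L23
#> 3  Chr05_A        1  2000000 deletion     20       0.300     2.0   L23
#> 4  Chr07_F        1  4500000 deletion     45       0.703     4.5    L1
#> 5  Chr08_B  8300001 13000000 deletion     47       0.000     4.7   all
#> 6  Chr08_E        1  1800000 deletion     18       0.698     1.8    L1
classify_individual(calls$layer)
#> [1] "chimeric"
```

Six deletions are recovered at bin resolution. Four sit in the 0.7 band
(epidermis-only), two in the 0.3 band (inner layers); the Chr08_B call at
dosage 0 is a region where the simulator implanted overlapping L1 and
L2/3 deletions, i.e. a compound full loss. The mixture of bands makes the
individual chimeric.

The packaged fixtures reproduce published worked examples: the indel table
of the two low-menthol mutants (`mint_indel_table()`) classifies to its
printed layers with full leaf/root concordance, and
`shared_deleted_regions()` recovers their single shared deleted haplotype
region (`Chr11_D`, first 2.5 Mb — the segment containing the dominant
menthone:menthol reductase allele).

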
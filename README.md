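# mratax

Integrative species delimitation for morphometricians and molecular
taxonomists: **multivariate ratio analysis (MRA)** of linear body
measurements combined with **DNA-barcoding distance analysis**, as used to
untangle cryptic insect species (the motivating case is a group of
European paper wasps whose species differ in subtle body proportions but
separate cleanly at two genetic markers).

## What it computes

Morphometrics, on a table of strictly positive measurements (µm) with OTU
and sex labels:

* **isosize** — geometric mean of all characters; the size axis
  `u = (1,…,1)/√p` in log space;
* **shape PCA** — covariance PCA of log-shape (log data minus the
  specimen's own log mean): a PCA "in the space of all ratios",
  unsupervised, at most `p − 1` informative components;
* **PCA and allometry ratio spectra** — PC loadings, and OLS slopes of
  log character on isosize, on one axis with 68% bootstrap intervals;
  the two characters at opposite extremes form the informative ratio;
* **LDA ratio extractor** — exhaustive search over all `p(p−1)/2`
  character pairs for the ratio maximising the standard distance
  `D(r) = |rᵀ(μ₁−μ₂)| / √(rᵀWr)` (`W` = pooled within-group covariance),
  reported with per-group raw-ratio ranges, an overlap flag, and
  **δ = D(u)/D(d_shape)** — near zero when separation is shape-driven,
  not size-driven.

Molecular, on aligned FASTA with OTU labels:

* closed-form pairwise **GTR distances**
  `d = −tr(Π log(Π⁻¹ F̂))` with pairwise deletion (plus p-distances);
* **barcoding-gap summaries** (max within-OTU vs min between-OTU distance,
  nearest neighbour, gap flag);
* **simple indel coding** (one binary character per distinct internal gap
  run, classified parsimony-informative / autapomorphic / constant).

Seeded generators produce multi-group log-normal measurement tables
(latent size factor, zero-sum shape offsets, allometric slopes; calibrated
to published per-group moments bundled in `inst/extdata/`) and GTR-evolved
alignments with planted indels, so the full pipeline runs and is tested
with no downloads. `run_pipeline()` joins both evidence axes into a
per-OTU-pair verdict table and byte-reproduces all outputs for a fixed
seed.

## Worked example

```r
library(mratax)

# two synthetic groups, ratio tib3.l:msp.l planted at standard distance 6
tab <- planted_ratio_table(c("tib3.l", "msp.l"), d_true = 6, n = 30, seed = 42)
best_ratio_search(tab, "A", "B")
#> <discriminant_report> A vs B (female)
#>   best ratio msp.l : tib3.l
#>   range A: 0.8332-0.9544 (n = 30)
#>   range B: 0.9811-1.267 (n = 30)
#>   standard distance 5.251, delta 0.006, overlap: no
```

The search recovered the planted pair; the group ranges do not overlap, so
the ratio is key-ready; `D = 5.25` estimates the planted 6 from n = 30 per
group; δ = 0.006 says the separation is shape, not size.

```r
spectrum_best_pair(pca_ratio_spectrum(tab, pc_index = 1, n_boot = 1000, seed = 42))
#> [1] "tib3.l" "msp.l"

aln <- gen_alignment(seq_gen_spec(data.frame(label = c("A", "B"), n = 4),
                                  length = 1500, between = 0.026,
                                  within = 0.002, seed = 42))
barcoding_gap_summary(distance_matrix(aln, "gtr"))
#> <gap_summary> per-OTU (distances in %):
#>  otu n within_max nearest_otu between_min gap_flag
#>    A 4        0.4           B        2.92     TRUE
#>    B 4        0.4           A        2.92     TRUE
```

Within-OTU divergence (0.4%) sits far below the between-OTU minimum
(2.92% at a target 2.6%): a positive barcoding gap on this marker.

End-to-end, from files:

```r
cfg <- pipeline_config(measurements = "measurements.csv",
                       alignments = list(cox1 = "cox1.fasta",
                                         its1 = "its1.fasta"),
                       n_boot = 1000, seed = 42, out = "results/")
run_pipeline(cfg)   # scores, spectra, suite, distances, gaps, verdicts.tsv
```

or from the shell via the installed CLI
(`exec/mratax`, JSON configs):

```sh
mratax run --config pipeline.json
mratax ratio-extract --input table.csv --sex female \
       --group1 helveticus --group2 bischoffi --out suite.tsv
mratax distances --model gtr --aln aln.fasta --otus map.tsv --out d.tsv
```

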
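# mitochip

Screening transcription-factor occupancy on the mitochondrial genome from
strand-specific ChIP-seq.

## The problem

ChIP-seq libraries show apparent enrichment over chrM in nearly every
experiment, most of it artifactual: the D-loop/control region is
preferentially captured in libraries regardless of the factor assayed, and
NUMTs confound mapping. Genuine punctate occupancy has a diagnostic
signature — plus-strand read 5′ ends pile up ≈ f/2 upstream and
minus-strand 5′ ends ≈ f/2 downstream of the bound site, where f is the
library fragment length. `mitochip` turns that signature into a scored
screen and surrounds it with the infrastructure needed to trust a call:

- **synthetic data** — a deterministic simulator for circular genomes with
  planted motifs, occupancy sites (asymmetric strand-shifted 5′ pileups),
  D-loop-like symmetric artifacts and NUMT-like duplications;
- **mappability** — the k-mer self-mapping track (k = 36) under a
  `-v 2 -k 2 -m 1 --best --strata`-style uniqueness contract, verified
  against a brute-force oracle;
- **tracks** — strand-specific full coverage and base-resolution 5′-end
  counts from SAM/BAM, with modular wrap, paired-end duplicate collapsing
  and single-end retain-all;
- **occupancy screen** — candidate regions above a fold threshold,
  classified by strand cross-correlation: `best_lag` near the fragment
  length with a correlation gain ⇒ `occupancy_like`; symmetric ⇒
  `artifact_like`; D-loop mask ⇒ `masked`;
- **profile model** — a BPNet-style dilated convolutional
  sequence-to-profile network (multinomial profile NLL over both strands
  jointly + MSE on log total counts), implemented from scratch with exact
  backprop, trained with contig-grouped cross-validation and used to
  corroborate observed calls;
- **evidence integration** — cross-dataset aggregation into
  orthogonal-evidence tiers (two different antibodies, or antibody +
  endogenous tag ⇒ `orthogonally_replicated`), with discordance flags and
  profile clustering.

## Worked example

```r
library(mitochip)

## a 16.6 kb circular genome with five occupancy sites and one
## D-loop-like artifact inside a mask around the origin
g     <- generate_circular_genome(16569, gc_content = 0.44, seed = 1)
pos   <- c(2000L, 5000L, 8000L, 11000L, 14000L)
sites <- truth_sites(c(pos, 500L), c(rep("+", 5), "both"), NA, 20,
                     c(rep("occupancy", 5), "artifact"))
masks <- data.frame(start = 16000L, width = 1200L, label = "D-loop")

aset <- simulate_reads(g, sites,
                       sim_config(50000, fragment_length_mean = 200,
                                  background_fraction = 0.5, seed = 11))
res  <- screen_dataset(aset, g, masks = masks)
res$report[, c("center", "fold", "best_lag", "score", "label")]
```

```
  center     fold best_lag    score          label
1    505 11.85697        0 0.000000         masked
2   1999 29.50788      200 1.044389 occupancy_like
3   4999 30.19030      200 1.042828 occupancy_like
4   8000 28.62303      200 1.040706 occupancy_like
5  11000 29.47515      200 1.045930 occupancy_like
6  14000 29.92485      200 1.048606 occupancy_like
```

Reading the output: each planted site is recovered as one `occupancy_like`
call within a few bases of the truth, with `best_lag = 200` — the
simulated fragment length — and a large correlation gain (`score`). The
symmetric artifact at position 500 shows `best_lag = 0`, the D-loop
signature, and sits inside the configured mask, so it is labelled
`masked` (it would be `artifact_like` without the mask). `fold` is peak
coverage over the median mappable background.

(The `center`/`fold` values above are from one run of this exact code;
your numbers will match at the same seed.)

End-to-end demo (simulate → mappability → tracks → screen → figures →
manifest, ~30 s):

```r
run_pipeline(demo_config(seed = 1), "demo_out")
```

A command-line wrapper with subcommands (`demo`, `simulate`,
`mappability`, `tracks`, `screen`, `config-dump`) is installed at
`inst/cli/mitochip.R`.

## Design notes

See the methods vignette (`vignettes/mitochip-methods.Rmd`) for the model
assumptions, every tunable threshold with its default and rationale, what
the simulator does and does not emulate, receptive-field arithmetic for
scaled-down configurations, and known limitations.
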
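# torcscan

Phylogenetic profiling of TOR complex components across eukaryotes.

The TOR kinase signals through two complexes with distinct scaffolds:
TORC1 (defined by RAPTOR) and TORC2 (defined by RICTOR, often with SIN1),
with TOR and LST8 shared between them. Across the eukaryotic tree TORC1 is
almost universally conserved while TORC2 has been lost repeatedly,
predominantly in photosynthetic autotrophs. torcscan is for comparative
genomicists who want to map that kind of complex presence/absence pattern
across many proteomes and turn it into explicit loss-event counts:

* **Homology tiers.** Per-component profile models (position-specific
  log2-odds matrices built from reference alignments) score each proteome;
  the effective score per species and component is
  `max(overall_bits, best_domain_bits)` and is binned by the rubric
  ABS < 100 ≤ L < 150 ≤ M < 300 ≤ H. Real HMMER3 runs plug in through a
  `--domtblout` parser.
* **Complex calls.** RAPTOR ⇒ TORC1; RICTOR (± SIN1) ⇒ TORC2; dataset-wide
  co-occurrence rules (SIN1 never without RICTOR; RAPTOR/RICTOR always with
  TOR and LST8) are checked and violations reported.
* **Read rescue.** Absences that contradict close relatives in
  low-completeness proteomes are re-tested against short peptide fragments
  (E ≤ 1e-10, bits > 50, domain overlap; ~70% identity for sub-10-residue
  matches), yielding tier P.
* **Dollo loss inference.** On a rooted (multifurcating) taxonomy tree, a
  single-gain irreversible-loss model gives the minimum number of
  independent losses per component and complex, the loss edges themselves,
  and the root (LECA) state.
* **Summaries.** Architecture composition per clade and trophic-strategy
  composition per architecture class, as tidy tables and ggplots.
* **Synthetic data.** A generator that emulates every input — clade-
  structured trees, planted irreversible losses, divergent homologs among
  decoys, degraded proteomes, peptide reads, trophic labels — so the whole
  pipeline is testable end to end.

## Worked example

```r
library(torcscan)
library(dplyr)

sim <- simulate_torc_dataset(sim_config(n_tips = 20, seed = 42))
hits <- bind_rows(lapply(names(sim$proteomes), function(sp)
  score_proteome(sim$profiles, sim$proteomes[[sp]], sp)))
tiers <- call_tiers(hits, profiles = sim$profiles,
                    species = sim$metadata$species)
complexes <- call_complexes(tiers)
table(complexes$architecture)
#>       both TORC1_only TORC2_only
#>         15          2          3

losses <- count_losses_per_trait(tiers, sim$tree)
losses$summary
#> # A tibble: 7 x 7
#>   trait  n_losses root_state      n_tips_present n_tips_absent n_tips_unknown
#> 1 TOR           0 present_at_root             20             0              0
#> 2 LST8          0 present_at_root             20             0              0
#> 3 RAPTOR        1 present_at_root             17             3              0
#> 4 RICTOR        2 present_at_root             18             2              0
#> 5 SIN1          4 present_at_root             14             6              0
#> 6 TORC1         1 present_at_root             17             3              0
#> 7 TORC2         2 present_at_root             18             2              0
```

Twenty simulated species: every species keeps TOR and LST8 (zero losses,
both present at the root), TORC1 was lost once (3 descendant species
affected), TORC2 twice, and SIN1 — which can only occur where RICTOR does —
four times. `autoplot(losses$reconstructions$TORC2)` draws the cladogram
with loss edges highlighted; `plot_tier_matrix(tiers)` shows the
species-by-component tier heat map.

The same verbs run on real data: point `run_all()` (or the thin CLI in
`inst/cli/torcscan.R`) at a directory of proteome FASTAs plus reference
MSAs — or at HMMER `--domtblout` files — together with a Newick taxonomy
tree and a species metadata table, and it writes `tiers.tsv`,
`complexes.tsv`, `violations.tsv`, `rescue.tsv`, `losses.tsv`, the two
summary tables, per-trait annotated Newick trees, and a run manifest.

## Layout

* `R/` — simulation, profile search, tier calling, complex inference,
  rescue, Dollo reconstruction, summaries, pipeline orchestration, plots.
* `src/` — the position-specific local aligner (ungapped prefilter +
  affine-gap stage with domain masking), in C++.
* `vignettes/torc-profiling.Rmd` — models, parameters, and design choices.
* `tests/testthat/` — unit and property tests, including the oracle-backed
  Dollo checks and end-to-end recovery runs.
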
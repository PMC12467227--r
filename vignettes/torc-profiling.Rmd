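---
title: "Profiling TOR complex evolution: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling TOR complex evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torcscan)
library(dplyr)
```

## The problem

The TOR kinase acts in two distinct complexes. TORC1 is defined by its
scaffold RAPTOR; TORC2 by RICTOR, often accompanied by SIN1; TOR itself and
LST8 are shared. Across eukaryotes the two complexes have very different
evolutionary fates: TORC1 is almost universally retained, while TORC2 has
been lost repeatedly, most conspicuously in photosynthetic autotrophs.
torcscan turns the question "which species retain which complex, and how
many independent losses does that imply?" into a reproducible pipeline:

1. score each proteome against per-component profile models and convert the
   best bit score into a confidence tier (H/M/L/ABS);
2. derive TORC1/TORC2 presence per species from the component tiers;
3. re-examine absences that contradict close relatives in poorly assembled
   proteomes, using short peptide fragments (tier P on success);
4. reconstruct ancestral states under a Dollo model on a taxonomy tree and
   count independent loss events per component and per complex;
5. summarise complex architecture by clade and by trophic strategy.

## Homology scoring

A profile model is a position-specific log2-odds matrix built from a
reference alignment. Columns with at least 50% residue occupancy become
match columns; observed frequencies receive +1/20 pseudocounts against the
background, so a column seen $n$ times scores residue $a$ as

$$ s_j(a) = \log_2 \frac{(c_{j,a} + 1/20)/(n_j + 1)}{b_a} . $$

With the uniform background the consensus residue of a well-conserved
column contributes about 4 bits, so a 160-column family profile scores its
consensus near 650 bits and a homolog at 30% divergence still above 300.

Scoring a sequence is local alignment against that matrix in two stages,
the shape used by profile-search pipelines: a cheap ungapped best-diagonal
scan over every sequence, then a full affine-gap alignment (gap open 10,
extend 1 bits) with iterative masking to extract additional non-overlapping
domains, for sequences whose ungapped score reaches 40 bits. The 40-bit
trigger was calibrated against the ungapped null: the best local score of a
300-residue background sequence against a 160-column profile concentrates
around 12–18 bits (its maximum over 200 seeded draws was 24.7), so
background sequences never reach the gapped stage — which matters because
the reported `overall_bits` is the *sum* of accepted domains, and letting a
1,500-residue decoy accumulate eight 10–25-bit junk domains would push it
past the 100-bit detection floor. Domains below 10 bits are discarded;
both floors are arguments, not constants.

The rubric maps the effective score — the maximum of the overall and
best-single-domain bit scores, so neither a fragmented alignment nor a
single strong domain is penalised — to tiers using half-open bands:
below 100 absent (ABS), [100, 150) low (L), [150, 300) medium (M), 300 and
above high (H). The prose convention "between 100 and 150", "above 300"
leaves boundary membership open; half-open bands make every score map to
exactly one tier, so 150 is M and 300 is H. Real HMMER runs are ingested
with `parse_domtblout()`, which fills the same hit structure; tier
assignment downstream is identical for both routes.

Hits are additionally screened: a positive hit in a clade where every other
member lacks the component is demoted when its domain coverage fails (or,
when reference identities are available, when it matches out-clade
references better than in-clade ones) — the automated version of a manual
contaminant screen. Sole positives that pass are kept but flagged
`outlier_checked`, so genuine outliers are never deleted silently.

## Complex calls

`call_complexes()` encodes the decision rules: RAPTOR at any positive tier
implies TORC1; RICTOR implies TORC2; SIN1 supports but never drives the
TORC2 call; read-rescued (P) detections count as presence. Three empirical
co-occurrence constraints — SIN1 never without RICTOR, RAPTOR/RICTOR always
with both TOR and LST8 — are checked dataset-wide and reported, not
enforced: violating species keep their rule-derived calls and carry flags
for manual re-examination.

## Read rescue

An ABS call is only distrusted when three things line up: the species'
completeness score is below 0.70, the component is present at H/M/L in at
least half of the tip neighbours within 3 edges (or uniformly across the
rest of its clade), and short peptide reads are available. "Close
relatives" had to be made operational — a tip-to-tip radius of 3 edges
covers sisters and near-cousins on taxonomy trees, which is what a curator
would eyeball. Clade-consistent absence is accepted as a real loss and
never triggers rescue.

Fragment matches are accepted with the thresholds E ≤ 1e-10 and bits > 50,
plus overlap with an annotated domain region; matches shorter than 10
residues (the protein-level equivalent of a 30-nucleotide match, where
E-values and bit scores are unreliable) instead require ≥ 70% identity.
A component is rescued to tier P only when at least two accepted matches
land on non-identical reference intervals — independent evidence along the
protein, a reproducible proxy for case-by-case judgement. Rescue can only
turn ABS into P; it never touches H/M/L. Background-only fragments rescue
nothing in 200 seeded trials.

## Loss inference

Ancestral states are reconstructed under a Dollo model: the trait is gained
once and can only be lost. Under that constraint the minimum-loss labeling
is closed-form — a node is present exactly when some informative descendant
tip is present — and each maximal all-absent subtree under a present parent
is one independent loss event. A property test checks this against
exhaustive enumeration of all irreversible labelings on random trees of up
to 10 tips.

Taxonomy trees are full of polytomies. Each child of a polytomy is
evaluated independently, so k all-absent children under a present parent
count k losses — the conservative (maximal) reading of an unresolved node,
noted in the output rather than hidden.

Two unknown-data policies are supported because published narratives are
ambiguous about absences in poorly assembled genomes: `"absent"` trusts
every ABS call; `"missing"` treats ABS calls from species below the
completeness threshold that were never put through rescue as missing data,
which can only reduce the loss count (unknown-only subtrees inherit the
parental state and contribute no losses). Root-state inference follows from
irreversibility: presence under two or more distinct children of the root
forces presence at the root — the logic behind placing both complexes in
the last eukaryotic common ancestor.

## The synthetic-data generator

Every pipeline input can be simulated, with the statistical structure the
analysis assumes, so each stage is testable without downloads:

* **Taxonomy**: `n_tips` species partitioned into labeled clades, topology
  built by random 2–4-way agglomeration so polytomies arise as they do in
  taxonomy exports (one is guaranteed from 6 tips up).
* **Losses**: per component present at the root, each edge independently
  becomes a loss edge with `loss_prob_per_edge`, suppressed below an
  existing loss (no regain). Two refinements keep the truth identifiable:
  at every still-present node the draw is conditioned on at least one
  surviving child lineage, so the planted loss-edge set is exactly the
  minimal Dollo explanation of the tip pattern (without this, losses on
  all children of one node would be planted as k events but reconstructed
  as one, and parameter-recovery checks would be comparing
  apples to oranges); and SIN1 losses are planted on top of RICTOR's, since
  a SIN1 subunit cannot outlive its complex — which also makes generated
  data satisfy the co-occurrence rules by construction. At
  `loss_prob = 1` the conditioning is impossible and every root-child edge
  is simply lost.
* **Sequences**: reference alignments per component (160 columns, 6
  sequences at 2% divergence — sharp enough that the consensus scores ~650
  bits), homologs emitted at `divergence` substitutions/site among 50
  background decoys of 200–1,500 residues (defaults chosen for test speed
  and exposed in the config; real proteomes are one to three orders larger).
* **Degradation**: a `completeness` fraction of proteins retained and a
  `fragmentation_prob` chance of truncation to a 20–80% prefix/suffix,
  emulating the low-completeness regime that motivates rescue.
* **Reads**: 33-residue peptide fragments (a translated ~100-nt read)
  sampled uniformly along each present homolog with per-residue errors,
  plus background fragments; reads are emitted as peptides directly because
  the rescue classifier operates on protein alignments — six-frame
  translation would add untested plumbing, not logic.
* **Trophic labels**: TORC2-lacking tips are autotrophs with probability
  `trophic_assoc` (default 0.9, a strong association); TORC2-retaining tips
  with the complementary rate, so 1/4 is the exact null of no association.

Default loss rates (0 for TOR/LST8, 0.02 RAPTOR, 0.08 RICTOR, 0.10 SIN1)
encode the observed regime: both complexes ancestral, losses concentrated
on the TORC2 side.

What the generator does *not* emulate: indel evolution and domain
shuffling, paralogy and copy-number variation (explicitly out of scope for
the tier caller too), compositional bias, contamination, or genuinely
correlated loss of interacting genes beyond the SIN1⊆RICTOR rule. Passing
the recovery tests therefore shows the pipeline's inference machinery is
correct under its own model assumptions — not that real proteome annotation
noise is handled; that is what the domtblout/DIAMOND ingestion routes and
the completeness-aware policies are for.

## Numerical choices and problem sizes

Ties in best-hit selection break by higher domain coverage, then smallest
sequence id, so outputs are byte-stable under input reordering. All
intervals are half-open and 0-based internally, converted at format
boundaries (domtblout and DIAMOND coordinates are 1-based inclusive). The
fragment aligner reports matches only within E ≤ 1e-3 (the usual aligner
reporting default; E-values use the crude ungapped-theory form
$E = mn\,2^{-S}$). Empty proteomes, empty fragment sets (ABS with flag
`no_reads`), traits absent everywhere (zero losses), and unknown-only
subtrees are all defined rather than error cases.

Test and verification sizes were chosen to exercise the claims at
desk scale: exhaustive Dollo enumeration on 200 random trees of ≤ 10 tips;
parameter recovery on 50 seeded datasets of 30 tips at divergence 0.05,
per-edge loss probability 0.1 and full completeness (the regime in which
recovery should be exact — and is, in 100% of runs with zero tier errors);
200 background-only rescue trials. Dataset-scale census numbers from
surveys of hundreds of genomes are not reproducible at this scale and are
not claimed; the property-based checks above stand in for them.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_torc_dataset(sim_config(n_tips = 20, seed = 42))
hits <- dplyr::bind_rows(lapply(names(sim$proteomes), function(sp)
  score_proteome(sim$profiles, sim$proteomes[[sp]], sp)))
tiers <- call_tiers(hits, profiles = sim$profiles,
                    species = sim$metadata$species)
complexes <- call_complexes(tiers)
losses <- count_losses_per_trait(tiers, sim$tree)
losses$summary
autoplot(losses$reconstructions$TORC2)
```

## Known limitations

* One sequence per component per species: multiple copies and paralogs are
  not resolved.
* The in-package scorer is a position-specific local aligner, not a full
  Plan7 HMM; bit scales differ slightly from HMMER's, which is why real
  analyses should ingest domtblout files and why the wide rubric bands are
  doing the robustness work.
* The "clustering of bit scores" used when the rubric was originally drawn
  is an exploratory inspection of score distributions, not an algorithm; it
  is intentionally not implemented.
* Loss counting on polytomies is conservative (maximal); resolving the
  polytomy can only merge, never split, the reported events.
* No formal association test links trophic strategy to complex
  architecture — the summaries report proportions only, deliberately
  stopping where the descriptive evidence stops.
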
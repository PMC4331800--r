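---
title: "Inferring phage transcription strategies from genome sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring phage transcription strategies from genome sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetx)
```

## The problem

Many lytic bacteriophages encode their own sigma factor or RNA
polymerase. Infection then unfolds in temporal stages: the host RNA
polymerase (with its sigma70 factor) transcribes the phage's *early*
genes from bacterial-type promoters; a phage anti-sigma factor shuts the
host enzyme off; and the phage-encoded sigma factor takes over,
transcribing *middle* and finally *late* (structural) genes from
phage-specific promoters. Reconstructing this program normally requires
macroarray time courses and biochemical promoter mapping. phagetx
implements a purely sequence-based route: find the phage-specific
promoters, find the host-type promoters, and read the temporal program
off their layout.

The hard part is the phage-specific promoters. They are typically *well
conserved but present in very few copies* — a handful of ~10-12 bp
sites in a 40-90 kb genome. Multiple local sequence alignment (MLSA)
motif finders such as Gibbs samplers are tuned for the opposite regime
(ambiguous motifs present in most input sequences) and fail here, which
the package demonstrates with its own sampler baseline. The productive
observation is that low-copy, high-identity sites are *repeats*, and
pairwise local alignment of intergenic regions finds repeats directly.

## Pipeline overview

`infer_strategy()` chains the stages; each is exported on its own.

1. **Intergenic extraction** (`extract_upstream_regions()`). Upstream
   gaps longer than 50 bp are extracted and oriented in the downstream
   gene's transcription direction, so later scans search only the direct
   strand (the promoter motifs are not palindromic). Because promoters
   can overlap the 3' end of the upstream gene, 30 bp of flanking
   sequence are prepended to each region's 5' end. A gap between
   divergent genes is upstream of both flanks and yields two regions;
   a convergent gap yields none. On a circular genome the gap joining
   the genome ends — typically the long region separating the two
   divergent gene clusters — is included, and it is the *anchor* for
   repeat discovery: the "+" cluster downstream of it could not be
   transcribed unless it carried at least one promoter copy.

2. **Pairwise repeat discovery** (`repeat_search()`,
   `consolidate_motifs()`). The anchor region is locally aligned against
   itself and against every other region (Smith-Waterman with affine
   gaps; successive position-disjoint hits, minimum aligned length
   7 bp). Hit intervals that share at least half of the shorter interval,
   or that are linked by an alignment, merge transitively into candidate
   repeat sets; sets whose consensi agree at 80% best-offset identity are
   merged (a k-copy repeat otherwise surfaces as disjoint pairwise
   components). Significance is the expected number of L-bp words
   occurring at least k times in n bp of background,
   `E = 4^L P[Poisson(n 4^-L) >= k]`; four 12-mers in ~4.4 kb give
   E ≈ 3e-9.

3. **Supervised core scan** (`track_promoters()`). The discovered
   motif's central hexamer (core) is rescanned across all regions as a
   12 bp window (2 bp left flank, core, 4 bp right flank). Each window
   is scored against a profile built from the alignment-discovered
   instances (pseudocount 0.5) and kept when its exact score-tail
   p-value is below 0.05. Windows are classified **late** when the first
   two bases match "TG" with at most one mismatch *and* positions 9-12
   are exactly "TATA", else **middle**; the reported anchor coordinate is
   the window 5' end for late motifs and the core 5' end for middle
   ones. Alignment-discovered instances are carried through even if
   their core itself has a mismatch (their support is the alignment
   E-value, not the scan).

4. **Host sigma70 promoters** (`build_promoter_model()`,
   `scan_genome()`, `threshold_by_strand_bias()`). A composite model —
   log-odds matrices for the -35 and -10 hexamers, an optional -15
   element, and a spacer-length score — is normalised so the consensus
   -35 / 17 bp spacer / -10 configuration scores exactly zero and
   everything else below zero. The score threshold for reporting is
   inherently arbitrary, so it is chosen by *strand positional bias*:
   the most permissive threshold leaving no predictions on the
   structural cluster's strand. The biological reading: host-transcribed
   early genes must lie on the functional cluster's strand.

5. **Temporal classification** (`classify_genes_temporal()`,
   `strategy_report()`). Each gene inherits the class of the nearest
   upstream same-strand promoter within its strand cluster (sigma70 →
   early, middle motif → middle, late motif → late), propagated
   operon-style to the cluster boundary; strand switches are the only
   stop signals used. Genes downstream of both a sigma70 and a middle
   promoter — characteristically the phage sigma-factor gene — are
   labelled middle with a dual-promoter rationale. Genes with no
   upstream promoter in-cluster stay unassigned rather than guessed.

6. **MLSA baseline** (`gibbs_motif_sampler()`, `robustness_score()`).
   A classic hold-one-out site sampler with a final add/subtract sweep,
   used to demonstrate *why* the pairwise route is needed: its
   predictions are validated by robustness (mean best-offset identity of
   consensus strings across independent runs), which collapses in the
   low-copy regime where the pairwise method succeeds.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_len` (gap cutoff) | 50, strict | bp | shorter gaps cannot hold a promoter plus flanks |
| `fuse_len` | 30 | bp | promoter overlap into the upstream gene's 3' end |
| `min_hit_len` | 7 | bp | shortest conserved stretch worth reporting |
| match/mismatch/gap | +1 / -3 / -5,-2 | score | standard short-sequence local-alignment weights |
| core window | 2 + 6 + 4 = 12 | bp | TG segment, core hexamer, TATA position |
| `p_threshold` | 0.05 | — | reporting level for scan-only (middle) motifs |
| spacer support | 15-20, optimum 17 | bp | canonical sigma70 spacer range |
| `pseudocount` | 0.5 | counts | profiles from as few as 4 sequences |
| sampler `motif_len` | 9 (or 18) | bp | extended -10 analogue (or T7-type RNAP promoter) |
| sampler sweeps | 500 default; 150 in tests | — | converges long before this on desk-scale inputs |

The 50 bp cutoff is applied to the *unfused* gap, before fusion; the
fused 30 bp never count toward eligibility.

## The simulator, and what passing tests mean

`simulate_phage_genome()` generates the architecture the pipeline
targets at desk scale: a circular ~12-13 kb genome; 5 "+" (structural)
and 15 "-" (functional) genes with log-normal lengths around 400 bp;
a 1.2 kb origin-spanning intergenic region carrying 4 copies of the
late motif template `TGTGATGTTATA`; 6 middle cores planted in the gaps
of the downstream part of the "-" cluster; 8 consensus sigma70
promoters (17 bp spacers) in the upstream part, all on the "-" strand;
uniform base composition; planted copies exact by default
(`mutation_rate = 0`), since the promoter class being modelled is a
well-conserved repeat. Every plant is recorded in a truth table, so
precision and recall are computable end to end
(`evaluate_against_truth()`).

What the simulator does *not* emulate: real coding-sequence base
composition and codon structure, genome mosaicism, overlapping or
nested genes, operon-internal promoters, terminators, and promoters
whose conservation decays with distance. A perfect score on simulated
genomes therefore shows the machinery is correct under the stated
architecture, not that real genomes will be as clean; on real input the
supervised scan in particular can report additional statistically
significant core windows (they pass the same p < 0.05 bar that the
planted ones do).

## Numerical choices

* **Coordinates** are 1-based inclusive everywhere, matching
  R/Bioconductor convention and GenBank reporting; origin-spanning
  features on circular genomes are represented with `end < start`.
* **Alignment hits** are found by Waterman-Eggert-style masking: after
  each traceback the consumed positions are excluded and the DP is
  rerun. Ties between equal scores break toward the smallest start in
  the first sequence, then the second. In self-comparison only the
  strict upper triangle is searched and each repeat instance stays
  available once per role, so k copies surface as a chain of pairwise
  hits rather than mirrored duplicates.
* **Consolidation** links intervals only when they share at least half
  of the shorter interval — a 1-2 bp brush with an unrelated chance hit
  must not bridge two repeat families — and drops instances shorter
  than 70% of the set's longest before consensus, copy number and
  E-value are computed (short chance echoes otherwise corrupt the
  majority consensus). Instance alignment for the consensus allows
  overhanging offsets, with ties broken by overlap then absolute
  offset.
* **Exact p-values** discretise per-position log-likelihood-ratio
  scores on a 1e-3 lattice and convolve across positions; the observed
  score is computed on the same lattice so ties resolve consistently.
  Profiles with zero entries are rejected (use a pseudocount).
* **Spacer scores** are `log(freq(l)/freq(17))` with *no* pseudocount:
  an unseen in-support length scores -Inf (excluded) rather than being
  smoothed into pretending it was observed. A training set whose modal
  spacer is not 17 bp triggers a warning because consensus-zero
  uniqueness then fails.
* **Ambiguity codes** (N etc.) are accepted in genomes; any scanning
  window containing one is skipped and counted, and alignment scores
  them as mismatches.
* **The Gibbs sampler** applies a phase-shift move every 5 sweeps
  (slide all sites by up to ±2 bp when that improves the total site
  score), avoiding the classic shifted-registration trap; the final
  add/subtract sweep removes sites scoring below background and adds
  non-overlapping sites scoring above the retained-site mean. Same
  seed, same result, bit for bit.

## Open design decisions

* The supervised scan covers **all** intergenic regions by default, not
  only the "+" group, because middle promoters sit upstream of
  "-"-cluster genes; `core_scan()` takes an explicit region subset for
  the restricted behaviour.
* The long/short classification rule (TG segment within one mismatch
  *and* exact TATA suffix ⇒ late) is induced from the conserved-length
  difference between the two promoter classes; it is deliberately
  crisp so that class assignment is reproducible.
* Sigma70 model: exact score values depend on the training alignment,
  which users supply (`read_training_promoters()`); the package's
  built-in training profile is a synthetic stand-in for a large-scale
  E. coli sigma70 alignment, with conservation strong at the invariant
  positions and a 17 bp-modal spacer distribution. The reproducible
  object is the consensus-zero structure and the strand bias, not any
  particular score value.
* The -15 element is modelled as an optional 4-position matrix
  immediately 5' of the -10 hexamer (weight zero when training lacks
  it); its width is configurable via the training columns.
* Genes between the anti-sigma gene and the first middle promoter have
  no stated rule; they remain unassigned.

## Problem sizes

The test suite and the acceptance script run entirely on generated
data: simulated genomes of ~12-13 kb with 20 genes, 1,000 random
sequence pairs of length ≤ 15 for the alignment oracle, 500-promoter
training sets for parameter recovery, Monte-Carlo checks with 2x10^5
draws, and sampler ensembles of 18-38 runs at 150 sweeps on 20-40
sequences of 150-200 bp. These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite
stays quick on one CPU.

## Known limitations

* Origin-spanning *genes* (as opposed to intergenic regions) are
  accepted in annotations but not handled by the gap arithmetic;
  rotate the genome so no gene crosses the origin.
* The word-Poisson E-value assumes i.i.d. background; the
  composition-matched variant replaces 1/4 by the background match
  probability uniformly over word types, a homogeneous approximation.
* `threshold_by_strand_bias()` optimises the "+"-strand constraint
  only; when several thresholds satisfy it, the most permissive is
  returned, which can admit weak additional "-"-strand predictions.
* The sampler implements one site-sampling variant; it is a baseline
  for the robustness argument, not a replacement for dedicated MLSA
  software.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_phage_genome(seed = 42)
st <- infer_strategy(sim$genome, sim$genes, seed = 7)
st
autoplot(st)                      # genome layout with temporal classes
tidy(st$sigma70_model)            # model matrices, long format
st$report$narrative
```
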
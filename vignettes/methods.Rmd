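---
title: "Methods: simulating and calling bait-anchored repair junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling bait-anchored repair junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling decisions behind `baitjoin`: how the
synthetic libraries are constructed so that ground truth is exact, how the
junction caller recovers bait–prey junctions, and why the default parameters
look the way they do.

## The assay being modelled

The package models bait-anchored junction sequencing of double-strand-break
(DSB) repair at an antigen-receptor-like locus. A fixed "bait" DSB is induced
next to a J segment; linear amplification from a primer in the retained bait
flank reads across whatever the bait end was joined to (the "prey"): a V
segment end cut at its recombination signal sequence (RSS), the distal flank
of the bait's own break (a rejoin), or an unrelated locus (a translocation).
Each sequenced molecule therefore contains a bait prefix, an optional
untemplated insertion, and a prey suffix. The junction structure — how much
microhomology (MH) the two ends shared, or how many inserted bases separate
them — is the readout used to distinguish repair pathways: classical end
joining produces direct and short-insertion joints, alternative end joining
is biased toward MH-mediated joints (MH length > 1 defines the operational
MMEJ class here) and longer resections.

## Coordinates and geometry

Internally every position is 0-based and intervals are half-open; the tlx
dialect written to disk is 1-based inclusive. Two small geometry records keep
the simulator, the truth emitter, the caller and the tests on one convention:

* **Bait geometry**: the read runs from the primer's outer end toward the DSB
  (`dir` = ±1 on the reference). After `r_b` bases of bait-side resection the
  last sequenced bait base is `dsb − dir·r_b`.
* **Prey geometry**: `anchor0` is the junction base at zero resection and the
  prey read extends from `anchor0 + dir·r_p` in direction `dir`, away from
  the break. A V segment exposes two prey flanks: the coding end (CE, into
  the segment body) and the signal end (SE, into the RSS-side flank);
  which one joins the bait depends on the configuration (deletional vs
  inversional V) and on whether a hybrid joint formed.

`Junction` in a tlx record is the strand-aware first prey base; `B_Junction`
the strand-aware last bait base. The *resection offset* of a V-region
junction is the strand-normalised distance of its junction base from the
assigned V cut site (0 at a zero-resection coding-end joint, negative into
the coding body).

## The simulator: intended structure equals emergent structure

The central design constraint is that the structure the simulator *intends*
(say, an MH-3 joint) must be exactly what a maximal aligner *reads back* from
the noiseless sequence. Otherwise ground truth would be wrong by
construction and every downstream assertion meaningless. Three mechanisms
enforce this:

1. **Physically realised microhomology.** An MH-k junction is only placed at
   resection pairs `(r_b, r_p)` where the k terminal bait bases equal the k
   reference bases immediately upstream of the prey junction, *and* the
   flanking base on each side mismatches (single-base frontier blocks), so
   the overlap cannot be extended by chance. Direct joints need only the two
   blocks. `junction_sites()` enumerates admissible sites; the resection
   mixture assigns their weights.

2. **The flank guard.** `build_toy_genome()` re-draws the bases flanking every
   scission point so that, for every bait × V-flank pair, no chance
   bait-suffix/prey-prefix identity exists at the zero-resection corner and
   the two direct-joint blocks hold at (0, 0). When coding- and signal-end
   baits flank the same DSB, the two break-adjacent bait bases are pinned to
   be complementary first — otherwise the accumulated "must differ"
   constraints on the prey side are jointly unsatisfiable.

3. **Insertion admissibility.** An inserted sequence is accepted only if no
   shifted alignment can beat the true one under the caller's objective: the
   cumulative mismatch count of any `y` trailing read bases against the prey
   reference upstream must exceed `0.45·y` (and symmetrically for leading
   bases against the bait-path continuation), and accidental palindromy with
   either flank is rejected unless palindromy was intended.

Other simulator decisions:

* **Resection mixture.** Per-end resection is `0` with probability `w0`, else
  a geometric tail with the configured mean, truncated at `resection_max`.
  Bait-side resection is additionally censored at the primer-to-DSB headroom:
  molecules resected past the primer are never amplified, mirroring the
  assay. Because MH and direct joints are *conditioned* on sequence
  availability, their realised resection marginals deviate slightly from the
  closed form (the guard makes the (0,0) cell deterministically admissible
  while other cells are a ~9/16 Bernoulli thinning); insertion joints sample
  resections unconditionally and recover the closed form exactly.

* **Perfect rejoins.** A religation with zero resection on both ends
  reconstitutes the unbroken reference and is physically undetectable; the
  blocking rules exclude such sites, so every emitted rejoin truth record is
  detectable. In the degenerate limit `resection_w0 = 1` *no* rejoin junction
  is realisable; those events are emitted as seamless religations (the
  unbroken-allele read, `structure_kind = "none"`, no truth tlx record).

* **Noise and duplicates.** Substitution noise is applied after truth
  coordinates are recorded. Exact duplicates (for deduplication testing) are
  appended with `:dup` query names.

## The junction caller

`call_junctions()` fits, per read, a two-changepoint model: the read is a
bait-path prefix up to `t1 − 1`, an unaligned gap of `t2 − t1` bases, and a
prey alignment from `t2` to the end. For each candidate prey diagonal
(k-mer-seeded, both strands, the bait's own diagonal excluded) it minimises

```
SB[t1 − 1] + 0.45 · (t2 − t1) + SP[t2]
```

where `SB`/`SP` are prefix/suffix mismatch counts against the bait path and
the prey diagonal. Ties prefer the smallest `t2` (microhomology is attributed
to the prey, making `Qstart` prey-maximal) and then the largest `t1`.
`B_Qend` is computed separately as the identity-maximal rightward extension
of the bait alignment — it runs through shared MH bases and stops at the
first bait-path mismatch, which the simulator's frontier blocks guarantee to
exist on noiseless reads. On error-free input the caller is therefore exact
*by construction*; under substitution noise the changepoint objective absorbs
errors on either side of the junction, and the only residual discordances are
reads where an error adjacent to the junction makes a shifted fit genuinely
likelihood-optimal (logged with reasons by `junction_concordance()`, not
asserted away).

An earlier design that extended the bait alignment with a local
confirmation-window rule could not simultaneously satisfy error-free
exactness and high concordance under noise — any single-window rule either
refuses to absorb errors near the junction or extends past it; the global
changepoint fit replaced it.

The gap cost 0.45 per base makes a one-base junction shift (cost 1 mismatch)
strictly worse than the true fit but lets genuinely unaligned insertion bases
(expected mismatch rate 3/4 against random sequence) remain in the gap.

## Classification and metrics

`classify_junctions()` derives the joint structure from the query overlap
`B_Qend − Qstart + 1` (≥ 1: MH of that length; 0: direct; < 0: insertion,
tested for palindromy against both flanks), categorises junctions by position
(rejoin within the bait region; V-J within ±200 bp of a V cut site,
inclusive; intra-locus otherwise on the bait chromosome inside the locus;
translocation elsewhere, split receptor-locus vs spontaneous), votes the prey
end type (CE/SE) from the aligned prey bases with ties decided by the
junction base, and records the resection offset and sub-TAD.

The metrics panel reports V-J efficiency (V-J junctions / total reads), the
CE:SE ratio (`NA` when no signal ends — undefined, not infinite), the 41-bin
structure axis `MH20..MH1, direct, INS1..INS20` with the MMEJ fraction
(MH > 1), resection enrichment (`N(|d| ≤ 10) / N(|d| ≤ 100)`; exactly 1 when
nothing resects), sub-TAD usage, and translocation frequencies — *relative*
(per 500,000 reads, no deduplication) and *absolute* (distinct after
deduplication on `Rname`, `Strand`, `Junction`, `B_Junction`).

## Default parameters

The defaults describe a plausible alternative-end-joining library on a small
toy locus and are the package's own choices: 4% V-J joining, 50% rejoins,
0.4% translocations (60:40 receptor:spontaneous); structure weights
`direct 0.55, MH1 0.25, MH2 0.12, MH3 0.06, MH4 0.02`; a hybrid-joint rate of
1/3; resection `w0 = 0.8`, mean 30 bp, max 100 bp; 0.1% substitution error at
150 bp reads. The `"NHEJ"` preset shifts weight toward direct joints and
short insertions with shallow resection; `"MMEJ_dominant"` toward long MH
with deep resection.

## Limitations

* Substitutions are the only error mode; no indels, no quality model.
* One junction per read; no multi-break reads or resected-through junctions.
* The toy genome is i.i.d. random sequence apart from the flank guard; there
  are no repeats, so prey alignment is unambiguous by construction.
* Translocation partners are modelled as single points, not as a genome-wide
  breakage landscape.

## Reproducing the bundled example

```{r example}
library(baitjoin)
spec <- load_locus_spec(
  system.file("extdata", "toy_locus.bed", package = "baitjoin"),
  system.file("extdata", "toy_locus.yaml", package = "baitjoin"))
r <- run_pipeline(sim_config(n_read_pairs = 5000L, seed = 1L), spec)
print(r$metrics)
```
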
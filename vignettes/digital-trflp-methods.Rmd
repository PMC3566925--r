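---
title: "Digital T-RFLP fingerprinting: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital T-RFLP fingerprinting: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfid)
```

## The problem

Terminal-restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community by digesting fluorescently end-labeled 16S rRNA
amplicons with a restriction endonuclease and sizing the labeled terminal
fragments (T-RFs) on a capillary sequencer. It is cheap and reproducible,
which makes it attractive for time series over many samples — but a peak at,
say, 214 bp carries no taxonomic label by itself. Amplicon sequencing of
the *same* DNA extract supplies that label: every read can be digested *in
silico*, so the community's fingerprint can be reconstructed digitally
(dT-RFLP) with full knowledge of which organisms contribute to each
fragment size.

Two obstacles make the link non-trivial:

1. **Electrophoretic drift.** Capillary electrophoresis systematically
   reports terminal fragments a few bp *shorter* than their true length
   (typically 4–6 bp, varying with fragment length, purine content and
   secondary structure). Digital and experimental profiles are therefore
   offset.
2. **Sequencing noise.** Pyrosequencing-type errors — substitutions and,
   above all, ±1 homopolymer-length errors — scatter the reads of one
   organism across neighbouring fragment sizes, inflating the apparent
   richness of a digital profile.

`trfid` addresses both: noise is absorbed by clustering reads at 97%
identity into abundance-weighted representatives, and drift is estimated by
cross-correlating the binned digital profile against the experimental one
over integer lags, then correcting the whole digital profile by the optimal
lag.

## The processing model

The standard procedure runs, in order:

1. **Parsing and primer trimming.** Reads from FASTA/FASTQ (or paired
   FASTA+QUAL); the forward primer is matched at the read start with IUPAC
   ambiguity (one mismatch allowed by default), the reverse primer's
   reverse complement is trimmed from the 3' end when present.
2. **Quality filtering.** Keep reads of 300–500 bp whose *mean* PHRED
   score is ≥ 20. The threshold is interpreted as a mean because per-base
   truncation is a different operation with different consequences for
   fragment sizes; a mean of 20 corresponds to a 1% expected error per
   base (`phred_error_prob(20)` = 0.01).
3. **Denoising.** Greedy identity clustering (`denoise_cluster()`):
   dereplicate, order unique sequences by descending duplicate count (ties
   lexicographically, so results are reproducible without any seed), then
   first-fit assignment at ≥ 97% identity. Identity is matches over
   alignment columns of an ends-free alignment scored +1/−1/−1 — linear gap
   costs deliberately penalize exactly the homopolymer indels the step must
   absorb, while free terminal overhangs keep reads of unequal length
   comparable. Singletons are retained. After membership is fixed, the
   cluster *representative* is chosen among members by highest duplicate
   count, then highest mean base quality, then lexicographic order. The
   rationale: with variable read lengths nearly every noisy read is unique,
   so the greedy founder is an arbitrary member that may itself carry an
   indel upstream of the restriction site; picking the cleanest member
   keeps one founder's error from shifting the entire cluster's fragment by
   a base pair.
4. **Mapping.** Every representative is aligned against every reference
   record with exact affine-gap Smith–Waterman (match +1, mismatch 3, gap
   open 5, gap extend 2 — under which a perfect full-length hit of an
   *L*-bp read scores *L*), in both orientations. The single best hit is
   kept; clusters scoring below 150 leave the pipeline. An exact exhaustive
   search replaces a heuristic seeded aligner deliberately: reference
   panels at this scale are 10²–10⁴ records, exactness is cheap, and a
   heuristic's scores approximate the same quantity. The normalized score
   divides by the full read length, not the alignment length.
5. **Digestion.** `first_cut()` scans each representative 5'→3' for the
   first recognition-site occurrence; the fragment size is the site index
   plus the enzyme's cut offset (plus a configurable `origin_offset`, see
   below). Site-free sequences are discarded and counted. Fragment counts
   are cluster sizes ("centroid inflation"), grouped by integer size.
6. **Comparison.** Profiles are binned at 1 bp over 50–500 bp (sub-50 bp
   fragments are outside the electropherogram's calibrated range) and
   cross-correlated over lags −20…+20 bp with cosine normalization;
   `apply_shift()` moves the digital profile by the optimal (or
   user-supplied) lag; experimental peaks are matched greedily to shifted
   digital peaks within ±1 bp.
7. **Annotation.** Each digital T-RF gets a ranked table of contributing
   phylotypes grouped by reference accession: read counts, percent
   contributions (1 decimal), representative SW scores, accession, OTU id.

The "filtered" variant skips step 3; "raw" additionally sets the SW
threshold to 0. Comparing the three quantifies what denoising buys: on
noisy synthetic reads the raw profile is several-fold richer than the
denoised one, entirely through error peaks.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_phred` | 20 | PHRED | 1% expected error per base |
| `min_len`, `max_len` | 300, 500 | bp | amplicon window; shorter reads bias T-RF proportions |
| `cluster_identity` | 0.97 | fraction | conventional OTU radius; absorbs sequencing error without merging taxa |
| `min_sw_score` | 150 | score | practical working range 100–250; 0 disables filtering |
| `max_lag` | 20 | bp | drift is 4–6 bp; the window must contain it with margin |
| `match_tolerance` | 1 | bp | residual sub-bp sizing error after a single global shift |
| `origin_offset` | 0 | bp | re-adds trimmed primer bases to fragment sizes if desired |

**Length origin.** Whether fragment sizes should count from the first base
after the primer or from the primer's 5' end is a convention, not a fact:
any constant offset is absorbed by the cross-correlation lag, so the choice
only relabels the drift estimate. Sizes are counted from the first base of
the processed read, and `origin_offset` exposes the other convention.

**Cross-correlation normalization.** The coefficient divides by the global
norms ‖d‖·‖e‖ rather than per-overlap norms, so values are comparable
across lags, bounded by 1, and exactly 1 for a pure translation. A Pearson
variant (centering each vector) behaves nearly identically on sparse
non-negative fingerprints but loses the translation-exactness property.
`coefficient(l)` is defined as the similarity between the digital profile
*shifted by l* and the experimental profile, so the optimal lag feeds
`apply_shift()` directly and comes out negative (≈ −drift).

**A single global lag** is applied rather than per-fragment drift models:
published per-fragment corrections still carry standard deviations above
1 bp, so fragment-wise shifting would not beat a global shift plus a ±1 bp
matching tolerance.

## Numerical conventions

- Fragment sizes are integer bp everywhere (electropherogram bins);
  rounding is half-up, as are printed percentages (1 decimal for
  contributions, 3 for normalized scores). Independent per-row rounding
  can make a contribution column sum deviate from 100 by up to 0.05 per
  row; rows are **not** adjusted to force the sum, matching how such
  tables are conventionally printed.
- Ambiguity codes: in recognition sites they expand to explicit base sets;
  an `N` in a read never completes a site (conservative — uncertain bases
  must not create fragments). In alignment scoring, only unambiguous equal
  bases reward a match.
- Mapping ties between references resolve to the earlier database record
  (logged); cross-correlation ties resolve to the smallest |lag|, then the
  negative lag; peak-matching ties at equal distance take the smaller
  digital size.
- Degenerate inputs fail loudly: empty profiles, zero-norm vectors, empty
  databases and duplicate accessions are errors, not silent results.

## The synthetic-data generator

`make_reference_db()` builds reference sequences whose *first* recognition
site is pinned at a chosen position, so every taxon's true fragment size is
known by construction. Defaults: 6 taxa, 480 bp references, sites spread
over 60–240 bp so each fragment terminates inside even the shortest (300
bp) read — mirroring real HaeIII bacterial fingerprints, whose fragments
concentrate below 300 bp. `simulate_reads()` draws reads as 5' reference
prefixes (uniform 300–480 bp), with per-base substitutions (default 0.005)
and ±1 homopolymer-length errors at runs ≥ 3 bp (default 0.02 per run) —
the dominant pyrosequencing error mode; clean bases get Q40, edited bases
Q10, exercising the quality model. `derive_etrflp()` produces the matching
"experimental" profile: true sizes shifted *down* by the drift (default
5 bp, inside the observed 4–6 bp range), a detection floor (default 0.5%)
removing peaks a real electropherogram would miss, then renormalization.

What the generator does *not* emulate: chimeras, primer bias, flowgram
noise structure beyond ±1 homopolymer errors, pseudo-T-RFs from undigested
single-stranded amplicons, and the per-fragment (length- and
purine-dependent) component of drift. Passing tests therefore demonstrate
the pipeline's arithmetic and its robustness to the modeled error modes,
not performance on any particular environmental sample.

Validation problem sizes were chosen to keep the full suite comfortably
fast while leaving sampling noise visible: 100 seeded drift-recovery
communities of 60 reads each across drifts 3–6 bp, 150–300 reads for
ground-truth and denoising checks. The acceptance script runs one
300-read community through the standard and raw procedures.

## Known limitations

- The denoiser is a sequence-space stand-in with the same 97% identity
  contract as flowgram-space denoisers; it does not model flowgram signal
  intensities, and `.sff` input is out of scope (convert to FASTA/FASTQ).
- Only the best mapping hit is kept; near-ties among references are logged
  but not reported as multi-hits.
- Exhaustive Smith–Waterman is quadratic per pair: appropriate for curated
  reference panels, not for full-database scans with 10⁵⁺ records.
- Double digests, methylation sensitivity and 3'-labeled fragments are not
  modeled.

## A worked miniature

```{r example}
ref <- make_reference_db(n_taxa = 4, length = 480, seed = 7)
ab <- c(0.4, 0.3, 0.2, 0.1)
sim <- simulate_reads(community_spec(ref$db, ab, read_count = 120, seed = 8))
ep  <- derive_etrflp(ref$truth, ab, drift = 5)

clusters <- denoise_cluster(quality_filter(sim$reads)$reads)
hits     <- map_clusters(clusters, ref$db)
digest   <- digest_dataset(clusters, hits$hits)
dprof    <- build_profile(digest)

xc <- cross_correlate(profile_to_vector(dprof), profile_to_vector(ep))
xc
shifted <- apply_shift(dprof, xc$optimal_lag)
match_peaks(ep, shifted)$percent_affiliated
head(annotate_trfs(digest, lag = xc$optimal_lag))
```
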
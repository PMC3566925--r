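# trfid

Digital T-RFLP fingerprints and T-RF affiliation from 16S rRNA amplicon
reads.

## The problem

Terminal-restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community: end-labeled 16S rRNA amplicons are digested with a
restriction enzyme and the labeled terminal fragments (T-RFs) are sized by
capillary electrophoresis, giving a profile of peaks (size in bp, relative
abundance in %). It is cheap enough to run on hundreds of samples — but a
peak carries no taxonomy. Amplicon sequencing of the *same* DNA extract
does: every read can be digested *in silico*, reconstructing the
fingerprint digitally (dT-RFLP) with the contributing organisms known for
each fragment size.

`trfid` is for microbial ecologists who run T-RFLP as a routine monitoring
method and sequence a subset of samples: it turns the sequencing data into
digital fingerprints, aligns them to the experimental ones, and tells you
which phylotypes sit under each experimental peak.

## Method in brief

1. Reads are primer-trimmed, filtered (300–500 bp, mean PHRED ≥ 20) and
   denoised by greedy clustering at ≥ 97% identity into abundance-weighted
   representatives.
2. Each representative is mapped by exhaustive affine-gap Smith–Waterman
   (match +1, mismatch 3, gap open 5, gap extend 2) against a
   taxonomy-annotated reference FASTA; best hit kept, SW score < 150
   removed.
3. In-silico digestion: the T-RF of a read is the distance from its 5' end
   to the first restriction-site cut (e.g. HaeIII GG^CC); fragments are
   pooled by integer size, weighted by cluster size, normalized to %.
4. Electrophoresis reports fragments 4–6 bp short of their in-silico size,
   so the digital profile d and experimental profile e (binned at 1 bp over
   50–500 bp) are aligned by cross-correlation over integer lags l ∈
   [−20, 20]:

       ρ(l) = Σᵢ d(i − l) · e(i) / (‖d‖ ‖e‖)

   The whole digital profile is shifted by the optimal (most negative-lying,
   typically −4…−6 bp) lag, and experimental peaks are matched to shifted
   digital peaks within ±1 bp.
5. Each T-RF gets a peak-annotation table: contributing phylotypes ranked
   by read count, with % contributions, SW scores and accessions. Richness
   and Shannon H′ (natural log), per-enzyme density reports and a
   six-enzyme screening mode (HaeIII, AluI, MspI, HhaI, RsaI, TaqI) support
   designing new fingerprinting protocols.

A seeded synthetic-community generator (reference database with pinned
restriction sites, error-bearing reads, drifted "experimental" profile)
makes the whole pipeline testable without any external data.

## Worked example

```r
library(trfid)

ref <- make_reference_db(n_taxa = 4, length = 480, seed = 7)   # known T-RFs
ab  <- c(0.4, 0.3, 0.2, 0.1)
sim <- simulate_reads(community_spec(ref$db, ab, read_count = 120, seed = 8))
ep  <- derive_etrflp(ref$truth, ab, drift = 5)                 # "lab" profile

clusters <- denoise_cluster(quality_filter(sim$reads)$reads)
hits     <- map_clusters(clusters, ref$db)
digest   <- digest_dataset(clusters, hits$hits)
dprof    <- build_profile(digest)

cross_correlate(profile_to_vector(dprof), profile_to_vector(ep))
#> <trf_xcorr> optimal lag -5 bp, max coefficient 0.999 (window -20..+20)
```

The injected 5-bp drift is recovered exactly. Shifting and annotating:

```r
xc      <- cross_correlate(profile_to_vector(dprof), profile_to_vector(ep))
shifted <- apply_shift(dprof, xc$optimal_lag)
match_peaks(ep, shifted)$percent_affiliated
#> [1] 100

annotate_trfs(digest, lag = xc$optimal_lag)[, c(1, 2, 5, 6, 10)]
#>   dtrf_size shifted_size count contribution  otu_id
#> 1        62           57    49          100       1
#> 2       122          117    34          100       2
#> 3       182          177    24          100       3
#> 4       242          237    13          100       4

profile_indices(shifted)
#> richness 4, Shannon H' 1.2857
```

Every experimental peak is affiliated, each digital T-RF is contributed by
exactly one phylotype (an error-free-dominated toy community), and the
fingerprint's diversity indices follow.

For real data, replace the synthetic inputs with your own files:

```r
cfg <- pipeline_config("reads.fastq", "greengenes_subset.fasta", "etrflp.csv",
                       out_dir = "out", procedure = "standard",
                       fwd_primer = "AGAGTTTGATCMTGGCTCAG")
res <- run_pipeline(cfg)   # writes stats, profiles, mirror data, annotations
```

A command-line front end with the same capabilities ships in
`inst/scripts/trfid.R` (subcommands `run`, `synth`, `screen-enzymes`,
`compare`).

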
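---
title: "Detecting and characterizing clustered somatic mutations"
author: "ClusteredMutations package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing clustered somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClusteredMutations)
```

# The problem

Most somatic mutations in a cancer genome are scattered approximately
independently, but a biologically important minority arrive in clusters:
doublet- and multi-base substitutions from single damaging events, diffuse
clustered hypermutation (omikli), and longer strand-coordinated showers
(kataegis) that frequently mark the action of the AID/APOBEC3 deaminase
family on single-stranded DNA. Kataegis co-locates with structural-variant
breakpoints, and on circular extrachromosomal DNA (ecDNA) it recurs —
ecDNA-resident kataegis is called kyklonas. Whether two nearby mutations
constitute a "cluster" depends on the sample: a hypermutated tumour has
small inter-mutation distances everywhere, so a fixed distance threshold
would misclassify wildly across samples.

This package implements a per-sample, simulation-calibrated detector for
clustered substitutions and indels, the downstream subclassification
(DBS / MBS / omikli / kataegis / other, clustered indels), proximity
modelling against structural-variant breakpoints, kyklonas analysis on
focal amplifications, mutational-spectrum matrices (SBS96, SBS288, ID83),
greedy signature decomposition, and the RTCA/YTCA APOBEC3 enrichment score.

# The model and procedure

## Background model

The null hypothesis for a sample is that its mutations are placed at
random given their sequence context. `simulateReplicates()` re-places
every mutation at a uniformly random position on its own chromosome that
carries the same ±2 bp pentanucleotide (matches on either strand are
accepted), 100 times by default. Every replicate conserves exactly the
per-chromosome burden and the per-context counts; variant allele
frequencies (VAFs) travel with the mutations unchanged. Whether simulated
positions may sit on either strand of the pentanucleotide match is not
fixed by the method's description; both strands are accepted here, which
doubles the candidate pool and cannot bias inter-mutation distances.
Transcriptional-strand preservation is not applied during shuffling: strand
ratios affect spectra, not positions, and the calibration consumes only
positions.

## The IMD cutoff

The intra-mutational distance (IMD) of a mutation is the distance to its
nearest neighbour on the same chromosome. For each candidate cutoff c the
sweep counts the real mutations with IMD < c and the same count in every
replicate, and accepts c when

* at most 10% of the below-cutoff mutations are expected by chance
  (mean simulated / real ≤ 0.10 — the "90% rule"), and
* a z-test of the real count against the replicate distribution gives a
  Benjamini–Hochberg adjusted q < 0.01 (the BH correction is applied
  across the candidate sweep, within the sample).

The largest accepted candidate becomes the sample's global cutoff, capped
at 10 kb. "Below" is the strict inequality IMD < c. Candidates are the
distinct observed IMDs *and their right-open successors* (IMD + 1): with
strict inequality, a cutoff equal to an observed IMD can never count that
IMD's own mutations, and in sparse streams (clustered indels especially)
the largest clustered spacing would otherwise always be lost at the
boundary. Sweeping the successors restores those mutations when the
acceptance criteria genuinely hold there; it changes nothing else. When
the replicate standard deviation at a candidate is zero the z-test is
replaced by an exact Poisson tail with the replicate mean — degenerate
nulls do occur at small c.

Regional mutation-rate heterogeneity is handled by a sliding 1-Mb window
(500-kb step — the window is described as "sliding" without a stated step;
half-overlap bounds the loss at window edges). A window whose real
mutation density exceeds ninefold the mean simulated density (simulated
density floored at one mutation per window) and which passes the same
90%/q-value test on its own mutations receives a window-specific cutoff,
re-derived within the window, capped at 10 kb and never below the global
cutoff.

If no candidate is accepted the profile records "no clustering
detectable" and downstream classification returns no events.

## Event grouping and subclassification

Maximal chains of consecutive mutations with pairwise distance below the
applicable cutoff (the window cutoff when the pair lies inside a flagged
window, else the global cutoff) form candidate events. Chains whose
adjacent VAF differences all stay within 0.10 are subclassified:

| size | distances          | subclass |
|------|--------------------|----------|
| 2    | all = 1            | DBS      |
| ≥ 3  | all = 1            | MBS      |
| 2–3  | at least one > 1   | omikli   |
| ≥ 4  | at least one > 1   | kataegis |

A chain with any adjacent VAF difference above 0.10 is classified "other"
in full — the VAF-inconsistent class is terminal. A splitting variant
(`splitOnVaf = TRUE`), where a VAF jump starts a new event instead, is
available for sensitivity analysis only. Chains with missing VAFs are
classified by the distance rules and flagged `vafUnavailable`. An event is
strand-coordinated when all member reference alleles are the same base.
Indels are calibrated and chained as a separate stream and labelled
`clustered_indel` without subclassification; mixed substitution/indel
chains are never formed.

The four-mutation kataegis boundary is motivated by a two-component
Poisson mixture over event sizes, truncated to support ≥ 2
(`fitEventSizeMixture()`). Whether the original mixture was truncated or
shifted is not stated; truncation is the natural choice for a size
variable bounded below at 2 and is flagged in the fit object. EM converges
when the log-likelihood gain falls below 1e-8; the iteration cap is 5000
because on cohort-scale samples from strongly overlapping components the
tolerance needs a few thousand iterations — a 500-iteration cap would
return a fit still mid-trajectory. Note that with component means near
2.1 and 4.4 the per-size posterior of the larger component cannot exceed
~0.5 at size 4 for any sub-dominant mixing weight: the mixture justifies
the boundary through its fitted cohort weights, not through a pointwise
posterior-domination argument.

## Structural-variant proximity

Each mutation's distance to the nearest breakpoint (interval-type SV
records contribute both endpoints) is modelled with a univariate Gaussian
mixture on log10(distance + 1); the modes of interest span 10 kb to
beyond 1 Mb, so a linear-scale mixture would be degenerate. The number of
components (1–5) is chosen by minimum BIC, with deterministic k-means
initialization under a seed. Distances are also normalized by the
per-chromosome expectation E = L / (2 (k + 1)) for k breakpoints on a
chromosome of length L — the mean distance from a uniform point to the
nearest of k uniform breakpoints or either end-segment boundary; the
Monte-Carlo suite verifies a mean ratio of 1 under uniform placement. The
exact constant is not printed in the method's description; this convention
is recorded in output metadata. An event is SV-associated when any member
lies within 10 kb of a breakpoint.

## Kyklonas

A kataegic event is assigned to a focal amplification when it sits on the
amplicon body (≥ 1 member mutation inside an interval; a
majority-membership rule is available behind a flag, as partial-overlap
handling is not otherwise pinned down) or within 10 kb of an interval
endpoint. Kyklonas = kataegis on the body of a *circular* (ecDNA)
amplicon. When an event touches several amplicons all associations are
reported and the headline label follows the priority circular > BFB >
heavily_rearranged > linear. Event-mean VAF above 0.80 marks early
mutagenesis (the region was mutated before clonal amplification), below
0.50 post-amplification mutagenesis; the intermediate band [0.50, 0.80]
is reported explicitly. Enrichment of clustered events on amplicons is
tested by shuffling each event's dominant mutation (its most frequent
substitution type, ties broken lexicographically) with the
context-preserving simulator and comparing the on-amplicon count to the
shuffle distribution (z-score; BH across samples).

## Spectra and APOBEC3 scores

SBS96 counts pyrimidine-centred trinucleotide substitution channels;
SBS288 splits each channel by transcriptional strand (template / coding /
intergenic), and a mutation inside bidirectionally transcribed regions
contributes 0.5 to each strand channel, so total mass is conserved
exactly. ID83 classifies 1-bp indels by homopolymer length, longer indels
by tandem-repeat count, and deletions additionally by flanking
microhomology (maximal flank match); channel numbers count repeat units
including the deleted copy for deletions and pre-existing copies for
insertions.

Greedy decomposition refits non-negative weights (Euclidean least
squares) over the selected set plus each candidate signature and keeps
the best candidate only while the cosine-similarity gain is at least
0.01; cosine is the selection criterion only. The reference points for
judging cosine similarities — mean 0.75, 99th percentile ≈ 0.81 for
random non-negative vectors — are reproduced by
`randomCosineCalibration()` using i.i.d. uniform(0,1) entries in 96
dimensions (the sampling law and dimension are not stated where the
numbers are cited; uniform/96 reproduces the mean exactly, and the
empirical 99th percentile computes to 0.82 at two decimals).

The APOBEC3 score compares mutated TpCpA sites by their preceding base:
RTCA (R = A/G; APOBEC3B-preferred) versus YTCA (Y = C/T;
APOBEC3A-preferred), normalized by motif availability in the ±20 bp
windows around all C>N mutations (both strands):
E_RTCA = (M_RTCA · N_C) / (M_C · N_RTCA). Availability is evaluated from
windows extended ±3 bp so an edge motif sees its true genomic context;
a plain substring count would under-count motifs by 41/38 and inflate the
score by ~8%. Because every window is conditioned on a central mutated C,
the null value of both scores is ~1.05 rather than exactly 1 — the offset
is symmetric between RTCA and YTCA and cancels in the reported fold.

# The synthetic world

`truthSpec()` states a desk-scale world whose statistical structure is the
one the detector assumes: 2 chromosomes × 20 Mb, GC 0.40, ~5,000
background substitutions and 500 background indels placed inhomogeneously
over per-Mb rate multipliers (Gamma(10, 10), mean 1 — mild regional
heterogeneity), clonal/subclonal VAF structure (0.5 / 0.25, 20%
subclonal), injected events of every subclass with known labels, 30
breakpoints with a subset of kataegis placed within 10 kb, and focal
amplifications of all four classes carrying planted kyklonas counts
{0, 1, 2, 5}.

Two scaling choices matter and are deliberate:

* **Cluster spacings are compressed with the genome.** At 125 background
  mutations per Mb the background IMD scale is ~8 kb — roughly 40× denser
  than a typical whole genome. Injected cluster spacings default to ≤ 25
  bp so that the ratio between cluster IMD and background IMD, which is
  the quantity the detector measures, stays in the regime the method was
  designed for. Planting genome-realistic spacings (hundreds of bp) into
  a desk-scale background would test a regime no real sample occupies.
* **Amplicon footprints are reserved.** Breakpoints and non-amplicon
  events avoid amplicon intervals (±20 kb), so the planted per-amplicon
  counts are exact truth — biologically, kyklonas sit on the
  extrachromosomal element itself, and a reference-genome simulation has
  no other way of keeping "on-ecDNA" well defined.

APOBEC events are built directly on TpCpW motif runs of one strand, so
they are strand-coordinated by construction; UV doublets mutate CC→TT;
uniform-spectrum events exercise the non-APOBEC paths. Event VAF noise is
a truncated normal with sd 0.02 around the event mean so injected events
pass the 0.10 adjacency rule with margin — the tests target the
classifier, not the noise model. The kyklonas VAF law draws the event
mean above 0.80 with probability 0.1 and around 0.30 otherwise, giving
both early and post-amplification timing classes.

What the generator does *not* emulate: sequencing reads, mapping
artifacts, copy-number calling, replication-timing covariates, and real
genome composition (repeats, CpG depletion, isochores). A green test
therefore establishes the statistical machinery — calibration, grouping,
classification, counting — not robustness to caller artefacts or
reference-genome idiosyncrasies.

# Numerical choices

* Strict inequality IMD < c plus successor candidates (above).
* Poisson-tail fallback for zero replicate variance.
* Gaussian-mixture EM: sd floor 1e-3 on the log10 scale; BIC parameter
  count 3k − 1.
* Truncated-Poisson EM: moments-based deterministic initialization;
  degenerate inputs (all sizes equal) return a flagged C1 = C2 fit.
* Non-negative weight fitting by box-constrained L-BFGS-B on the residual
  sum of squares with analytic gradient.
* Collisions in a shuffle replicate are re-drawn per mutation, at most
  100 times, then an error is raised.
* All coordinates are 1-based inclusive internally; BED input is
  converted at exactly one boundary (`readIntervals()` /
  `readAmplicons()`).

# Known limitations

* The mean-recovery precision of the event-size mixture at the published
  component means is limited by identifiability: the components overlap
  strongly, and at n = 50,000 the maximum-likelihood estimate of the
  larger mean scatters by about ±0.2 across simulation seeds.
* q-value correction scope (across candidate cutoffs, per sample) is one
  of several defensible readings; it is recorded in the output metadata.
* Regional windows are rarely triggered in homogeneous desk-scale worlds;
  their test coverage relies on a constructed 16-Mb enrichment fixture.
* VCF input takes the first ALT allele of multi-allelic records.
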
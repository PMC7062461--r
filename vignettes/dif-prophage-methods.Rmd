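---
title: "Models and methods: dif-flanked gokushovirus prophage discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dif-flanked gokushovirus prophage discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gokuphage)
```

## The biological model

Gokushoviruses (Microviridae, subfamily Gokushovirinae) are small circular
ssDNA phages, long believed to be strictly lytic because no member encodes
an integrase. `gokuphage` implements a pipeline around a different
integration route: passive, host-driven recombination at the chromosomal
*dif* site. The *dif* site is a 28-bp sequence — an 11-bp XerC-binding arm,
a 6-bp central spacer and an 11-bp XerD-binding arm — where the host
tyrosine recombinases XerC and XerD resolve chromosome dimers. A phage
genome carrying its own *dif*-like motif can be integrated at this site by
the host machinery, and excised again the same way.

The genomic signature of such a lysogen is precise:

- the prophage sits immediately downstream of the chromosomal *dif*;
- the upstream (bacterial) *dif* is nearly canonical — at most one
  mismatch from the host consensus;
- the downstream copy is the phage's own *dif*: its XerC arm is conserved,
  while the spacer and XerD arm are divergent;
- the excised, circular replicative form carries the phage *dif* once and
  the bacterial *dif* not at all.

The package's components mirror this structure: a miner that finds capsid
loci and attachment-site repeats and excises replicative forms
(`find_capsid_loci()`, `find_flanking_repeats()`, `call_prophage()`,
`excise()`, `mine()`); a site classifier (`dif_grammar()`,
`classify_dif()`); an integration model (`integrate_phage()`,
`host_state()`); a PWM scanner with iterative motif discovery
(`build_pwm()`, `scan_pwm()`, `filter_hits()`, `iterative_search()`);
comparative assays (`pairwise_ani()`, `cluster_clades()`,
`identity_profile()`, `insilico_pcr()`, `genotype_bands()`); and a seeded
synthetic-genome generator with a ground-truth oracle (`sim_config()`,
`make_host()`, `make_phage()`, `plant_integration()`, `make_mag_set()`).

## Coordinate and sequence conventions

All coordinates are 1-based inclusive, the IRanges/Bioconductor convention;
BED output converts to 0-based half-open at the I/O boundary, GFF3 is
written 1-based. A single internal convention is what prevents off-by-one
drift, and in an R package that convention is the one every Bioconductor
container already uses.

Sequences are uppercase over `A,C,G,T,N`; `N` mismatches everything in
Hamming comparisons (conservative). Circular topology is carried as a
record flag and serialised as a `[circular]` FASTA header token, since
FASTA has no topology field. Rotation-invariant comparisons go through
`canonical_rotation()`: anchored rotation when a unique anchor (usually the
phage *dif*) is known, otherwise the lexicographically minimal rotation
(Booth's algorithm).

The canonical *dif* sequence shipped as the default
(`GGTGCGCATAATGTATATTATGTTAAAT`) is the E. coli chromosomal site from the
literature. It is a configuration value, not ground truth: every operation
accepts an override, and the grammar's component lengths are themselves
configurable.

## The prophage region convention

A called prophage runs from the first base **after** the upstream
(bacterial) *dif* through the **last base** of the downstream (phage)
*dif*. Under this convention the phage *dif* travels with the excised
genome and the bacterial *dif* stays behind, so
`excise(integrate_phage(...))` is an exact round trip (up to rotation) and
lengths are conserved at every step. This convention has to be fixed for
any length statement about excised genomes to be testable; it matches the
excision scheme in which amplification primers incorporate the phage motif
but exclude the bacterial one.

## Boundary detection and its fallback

The primary boundary criterion is a pair of identical 17-bp (default)
sequences, one in each 5-kb flank of the capsid locus, extended to maximal
identity and ranked by extended length, then by smaller enclosed interval,
then leftmost. The conserved part shared between a near-canonical bacterial
*dif* and a divergent phage *dif* is, however, often only the 11-bp XerC arm
plus a few spacer bases — shorter than any 17-mer. When no qualifying
repeat pair exists, the miner falls back to scanning both flanks with the
*dif* PWM and pairing the best upstream and downstream windows. Either way,
each boundary is anchored by the best PWM-scoring 28-bp window near the
repeat copy before classification, and a call is rejected (with a logged
reason) when the upstream site is not bacterial-like.

The capsid-locus threshold (default alignment score 125, BLOSUM62, affine
gaps 10/0.5) was calibrated as the maximum best-hit score over 100
unrelated 20-kb simulated genomes (observed 71.5) plus a comfortable
margin; genuine capsid matches score an order of magnitude higher.

## The integration-requirement model

`integrate_phage()` encodes the cooperative-binding requirement: insertion
happens only when the host's XerC **and** XerD are active and the phage
site is phage-like (both arms present, XerC arm within tolerance, default
2 mismatches). Everything else returns a typed refusal. Plasmid
complementation is modelled by `apply_complementation()`: an induced xerC
construct restores XerC, while an induced xerD construct restores XerD only
when the host state is flagged `xerD_complementable` — by default it is
not, reproducing the observed asymmetry between the two complementations
without inventing a mechanism; the flag is configurable. The model is
deliberately qualitative: it predicts which strain/phage combinations can
lysogenise at all (the zero pattern), not quantitative lysogeny
percentages, which depend on wet-lab kinetics outside this package's scope.

Arm-deletion constructs are built with `delete_dif_arm()`; both 17-bp
remnants (site minus XerC arm, site minus XerD arm) have the same length,
so `classify_dif()` resolves them by which hypothesis fits the canonical
components better.

## The PWM scanner and the rescue rule

*dif* sites are fixed-length and ungapped, so the site model is an ungapped
position weight matrix of the grammar width: column counts plus a
pseudocount (default 0.5) over a background (default uniform), scored as
log2 odds. A profile HMM adds insert and delete states that a fixed-length
ungapped site never exercises; for this motif class, match-state emissions
are the entire model, and the PWM expresses it exactly.

Two thresholds control scanning:

- **scan floor** (default log-odds 0): the lowest score reported at all.
- **primary threshold** (default `"auto"`): calibrated from the *exact*
  null score distribution, computed by per-column convolution on a 0.01
  lattice, such that the expected number of false hits per 5 kb scanned on
  both strands is `null_fpr` (default 0.05). For the canonical-trained PWM
  this gives a threshold near 12.2 log-odds units.

Every accepted hit must satisfy two rules. First, the identity rule: at
least 15 bases positionally identical (grammar frame, no shifts — the
conservative reading) to a **confirmed** motif. Second, the context rule:
hits inside coding sequence are rejected as likely false positives —
integration there would interrupt the gene — except inside the first 90 bp
of a VP4-role gene, the one coding location where such motifs are
tolerated. "Non-coding" is operationalised as overlapping no gene call on
either strand, since no length cutoff for "short non-coding region" is
defined; the 90-bp N-terminal window is likewise a quantification choice
(wide enough to hold a 28-bp site just downstream of a start codon) and is
configurable. Among accepted hits, those at or above the primary threshold
are **confirmed**; the rest are **potential**.

The distinction matters in the iterative search: only confirmed motifs can
vouch for further hits through the identity rule, while both confirmed and
potential hit sequences enter the PWM training set. A potential hit is,
by construction, a weaker claim — letting it anchor identity comparisons
would let chains of marginal matches bootstrap themselves into the motif
set. The identity rule is still a looser net than the calibrated score
threshold (a random 28-mer matches a fixed motif at 15 or more positions
with probability around 1e-4), which is why the context filter backs it
up; the `null_fpr` calibration and the 500-null-genome acceptance check
apply to confirmed hits.

`iterative_search()` repeats build-scan-filter rounds until a round adds
no new motif (or `max_rounds`), which lets a divergent motif found in one
genome unlock a still-more-divergent one elsewhere. Accepted hits
accumulate across rounds: a discovery made under an early PWM is never
dropped because a later, retrained PWM shifts a local score maximum by a
few bases.

## Comparative assays

`pairwise_ani()` aligns two rotation-normalised genomes globally (match 2,
mismatch −1, gap 10/0.5) and reports matching columns over aligned columns
excluding terminal gaps, as a percent. A single global alignment is exact
for genomes under 5 kb and sidesteps fragment-based ANI estimators; this
differs from BLAST-style tool ANI and is stated as such. Clades are
single-linkage components of the graph with edges at ANI strictly above
the threshold (default 95), labelled A, B, ... by decreasing size;
isolated genomes are singletons. `identity_profile()` computes per-column
mean pairwise identity over gap-free pairs — dips mark hypervariable
regions. `insilico_pcr()` matches primers exactly (a mismatch tolerance is
configurable, the 3'-terminal base must always match), reports products
inclusive of both primers, and yields origin-crossing products only on
circular templates; `genotype_bands()` turns per-genotype amplicons into a
band table with population fractions, the counting model behind
lysogen-fraction readouts.

## The synthetic generator and what it does (not) emulate

The generator encodes the study conditions: hosts of 100 kb (scaled to
12 kb in most tests; results do not depend on host length) with exactly one
planted *dif* at most one substitution from canonical; circular phages of
4047–4692 bp — the wider of the two plausible ranges for excised genomes —
with six genes in the order VP4, VP5, VP3, VP1, VP2, VP8 built by
back-translating fixed synthetic reference proteins; a phage *dif* in the
VP2–VP8 intergenic gap built as the canonical XerC arm plus a spacer/XerD
arm mutated at per-base rate 0.3. The phage *dif* is resampled (a ~1e-5
event at the default rate) to keep at least 15 of 28 bases identical to
canonical — the field's own criterion for a recognisable *dif* motif — and
at least 2 mismatches, so the site stays distinguishable from the bacterial
one; with the mutation rate set to 0 the site is exactly canonical.

Several guards make the ground truth authoritative rather than
probabilistic. Host backgrounds are resampled until no 17-mer of the
planted site recurs elsewhere on either strand. Phage and MAG builds are
resampled until the constrained ORF caller recovers every planted gene at
its exact coordinates; to make that achievable the generator places an
in-frame stop immediately upstream of each start codon and biases
synonymous codon choice towards codons whose reverse complement is a stop
(TTA, CTA, TCA), keeping the antisense strand stop-rich as in real coding
sequence. MAG motif plants are rejection-sampled so that coding plants
never introduce an in-frame stop and so that the annotation layer assigns
exactly the intended context label. Decoy repeats are built with exactly
10–14 bases identical to canonical.

Determinism: every operation draws from `withr::with_seed()` on a seed
derived from the configuration seed and the operation name, so a host and
a phage built from the same seed are reproducible *and* mutually
independent, and repeated calls are byte-identical.

What the generator does **not** emulate: realistic codon usage or GC
structure (background is i.i.d.), phylogenetic correlation among phages,
sequencing error, reads, or assembly artefacts. Passing recovery tests
therefore demonstrates the correctness of the operators' logic on genomes
with the assumed architecture, not robustness to the full messiness of
real assemblies.

## Numerical choices and tie-breaks

- ORF length includes the stop codon; the 110-bp minimum and 50-bp
  maximum overlap are applied to that length. Greedy selection is by
  decreasing length, ties by leftmost start, then `+` strand.
- Overlapping scan hits on the same strand resolve to the local score
  maximum; ties break to the `+` strand, then leftmost.
- Repeat pairs rank by longer extended match, then smaller enclosed
  interval, then leftmost upstream copy.
- Clade labels order components by size, then smallest member id.
- PWM scores for `N` take the column minimum.
- The exact-repeat seed stays at 17 bp even though the conserved XerC arm
  is shorter; the PWM fallback, not a shorter seed, covers divergent
  pairs, keeping the primary criterion strict.

## Problem sizes used by the test and acceptance suites

The acceptance suite runs 100 seeded integrations (12-kb hosts) for the
round-trip and boundary-recovery checks, 50 seeded MAG sets of 6 genomes
for motif recovery, 500 unplanted MAGs for the confirmed-hit
false-positive check, and 96 simulated infection trials per condition for
the lysogeny zero pattern. These sizes give exact (not asymptotic) checks
of the logical claims while keeping the default test run short; all scale
linearly if larger runs are wanted.

## Known limitations

- Rotation-free ANI on circular genomes relies on a shared anchor or the
  minimal rotation; two unrelated circular genomes without an anchor may
  align at an arbitrary rotation offset, lowering ANI for borderline pairs.
- `find_capsid_loci()` does not search across the origin of circular
  records; capsid genes are assumed not to span the breakpoint (the
  generator guarantees this, and prophages in linear host contigs cannot
  wrap).
- The greedy ORF caller is a stand-in for an interpolated-Markov-model
  gene finder: downstream consumers need coordinates and roles, not coding
  scores, but spurious short ORFs in real genomes would be noisier than in
  the simulated ones.
- The lysogeny model is a boolean predicate; it reproduces which
  conditions can integrate, never the quantitative percentages.
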
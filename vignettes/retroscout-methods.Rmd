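---
title: "retroscout: methods, parameters and design decisions"
author: "retroscout maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retroscout: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`retroscout` automates a discovery procedure for LTR retrotransposons that
was originally carried out by eye: find unannotated genomic regions whose
small-RNA signal is lost or qualitatively changed while their mRNA signal
increases in an RNAi-deficient mutant, confirm retrotransposon protein
motifs in them, define element borders from flanking direct repeats,
collect further genomic copies and solo-LTRs, group everything into
families and lineages, and characterise the small-RNA populations.  This
vignette documents the models behind each stage, the tunable parameters
with their defaults and rationale, what the synthetic data generator does
and does not emulate, and the places where the design was genuinely open.

# The discovery signature

All four coverage tracks (sRNA/mRNA × wild-type/mutant) must be
RPKM-normalised; the caller is deliberately depth-agnostic and refuses raw
tracks.  Windows of 500 bp step in 100 bp increments over 50 bp bins and a
window is flagged when both hold:

* **small RNA** — *lost*: wild-type density ≥ 5 RPKM **and**
  `(wt + 1)/(mut + 1) ≥ 4`; or *changed*: the pseudocounted ratio exceeds 4
  in either direction.  The minimum-density guard exists because a 4-fold
  ratio between two near-zero numbers is noise, not signal.  The *changed*
  branch captures loci where the mutant gains an alternative sense-only
  small-RNA population; note that under RPKM normalisation the magnitude of
  that gain reflects library composition (a mutant library dominated by a
  single family has concentrated RPKM), which is exactly what makes such
  loci stand out in depth-normalised data.
* **mRNA** — `(mut + 1)/(wt + 1) ≥ 2`.

Flagged windows merged across gaps ≤ 500 bp form a region.  Window-scale
detection is robust but blunt: a union of 500 bp windows overhangs a true
element by several hundred bases per edge.  Region edges are therefore
refined to the outermost 50 bp bin that individually passes the mRNA-gain
criterion.  Regions overlapping any existing annotation are discarded;
regions shorter than 1 kb are kept but marked, because the acceptance rule
applied between the signature and annotation stages is: *keep a region only
if it is larger than 1 kb and carries at least one retrotransposon protein
motif*.

None of the fold thresholds is canonical — the original identification was
manual — so all of them live in `signature_thresholds()` and are logged per
decision in the pipeline's `log.txt`.  The defaults (4× sRNA, 2× mRNA,
1 RPKM pseudocount) cleanly separate the effect sizes the generator plants
and are stated once here, not tuned per dataset.  The bin size is likewise
unstated in the source procedure; 50 bp is the package default and is
config-exposed.

# Protein-domain models

Domains are found by scanning all six reading frames with ungapped
position-specific scoring matrices.  A model column scores residue $r$ as

$$s_j(r) = \log_2 \frac{(c_{j,r} + 0.5) / (N + 10)}{1/20}$$

(pseudocount 0.5, uniform background).  A window must be a clean open
reading frame: any stop codon rejects the window outright, because intact
retroelement domains are encoded without interruption — this is also why
the synthetic generator preserves ORFs when it mutates (below).  Model
thresholds are calibrated empirically: the threshold is the
$(1-\alpha)$-quantile ($\alpha = 10^{-3}$, 1000 draws, fixed seed) of
scores of random background sequences of model length.  The calibration is
a substitute for the significance machinery of a full conserved-domain
search service and is deliberately permissive; two pipeline rules
compensate for its tail:

* the **direct-repeat anchor** uses only hits with positive total
  log-odds.  A hit whose summed bits are negative is *less* likely under
  the model than under background; and because the two LTR copies of an
  element are near-identical, any weak window that fires in one fires in
  both, which would drag the cassette envelope into the LTRs and truncate
  the repeat search.
* a **novel copy match** (from the genome-wide scanner) is upgraded to an
  element call only on a positive-log-odds hit, so that bare LTR copies a
  few hundred bases long are not promoted to spurious partials by a
  marginal window.

Weak hits still count toward the "≥ 1 motif" acceptance rule for signature
regions, which are additionally protected by the 1 kb requirement.
Overlapping hits of the same model reduce to the best-scoring one.  The
bundled profiles are synthetic (built from the generator's reference
cassettes; filenames prefixed `synthetic_`); `build_model()` accepts any
aligned protein FASTA so curated profiles can be substituted.

# Element borders and classes

Around the anchor (the positive-hit envelope) the flanks are searched for
direct repeats: shared 12-mers between the upstream and downstream flank,
chained by diagonal (±40, gap ≤ 600) and extended by banded local alignment
(match +1, mismatch −1, gap open −5, extend −1).  Pairs need ≥ 100 bp and
≥ 80% identity; the best pair maximises length × identity with ties broken
toward the smaller enclosed span, making the output deterministic.  The
100 bp / 80% / 5 kb-flank defaults are this package's choices (the original
procedure states no acceptance criteria for a repeat pair); they bracket
the geometry of known fission-yeast elements and are config-exposed.
`TG...CA` termini are reported as a flag but never required.  In the
pipeline the searched flank is truncated at the candidate region plus a
500 bp margin: elements cluster tightly, and a 5 kb flank would otherwise
reach a *neighbouring* element of the same family whose LTR could pair
across elements.

Classes follow structural evidence: paired LTRs + reverse transcriptase +
integrase ⇒ *full-length*, spanning the outer LTR bounds; ≥ 1 motif without
an accepted pair ⇒ *partial*; a lone LTR copy with no motif within 1 kb ⇒
*solo-LTR*.  For partials the pipeline reports the refined signal region
(clipped to include all hits) rather than the bare coding envelope: a
truncated element retains non-coding sequence beyond its outermost domain,
and the differential-transcription interval estimates that extent far
better — with the coding envelope alone, a single-domain fragment would
systematically under-cover its element.

# Genome-wide copies and solo-LTRs

The copy scanner seeds exact 15-mers on both strands, chains by diagonal
and extends with the same banded affine local alignment; matches need
≥ 200 bp and ≥ 70% identity, overlapping matches reduce to the best score,
and the query's own locus is excluded.  Solo-LTRs are found by running the
scanner with a family's LTR sequence alone (k = 12, ≥ 100 bp, ≥ 80%) and
removing matches within 1 kb of any domain-bearing call.  Scoring and
cutoffs are nucleotide-space heuristics standing in for a general-purpose
aligner's defaults; they are parameters, not claims.

# Families and lineages

Pairwise element identity is computed over the reverse-transcriptase,
RNase H and integrase nucleotide sequences: per shared domain a global
alignment (match +1, mismatch −1, gap −2), identity = matches over aligned
columns excluding terminal gaps, combined as a column-weighted mean.  Two
open readings were settled as follows: the comparison is in nucleotide
space (the 95% threshold then separates the planted within-family from
between-family divergence with a wide margin; amino-acid space is a config
flag away via your own models), and the > 95% rule is applied to the joint
(length-weighted) identity rather than per domain.  Families are the
single-linkage transitive closure of `identity > 0.95` — realised with
`hclust(method = "single")` cut strictly below 0.05 — which treats "same
family" as a transitive relation; complete linkage is an alternative
reading, noted but not implemented.  Elements lacking all three core
domains are excluded from clustering.  Family numbering follows the
leftmost genomic position of each family's representative (longest member),
so labels are invariant to input order.  Lineage assignment builds a
neighbour-joining tree (`ape::nj`) on `1 − identity` over family
representatives plus bundled reference triplets and labels each family by
its nearest reference in patristic distance.  Maximum-likelihood inference
and bootstrap support are out of scope by design.

# Small-RNA profiles

A read belongs to an element when it overlaps it by at least half the read
length (no rule is canonical; half-length is symmetric and insensitive to
read length) and multimapping reads count at every element they overlap.
Profiles record per-strand length histograms (15–35 nt), the sense
fraction, the global 5'U fraction plus a per-length composition table
(the source plots are per length class; both views are emitted), and the
modal length with ties broken toward the smaller length.  Classification:
*siRNA-like* requires modal length ∈ {22, 23, 24}, antisense fraction
≥ 0.2 and 5'U ≥ 0.5; *sense-degradation-like* requires a sense fraction
≥ 0.95 and not being siRNA-like; anything else, or fewer than 50 reads, is
*ambiguous*.  These numbers codify qualitative descriptions ("predominantly
23–24 nt", "almost exclusively sense") and are config-exposed in
`sirna_class_params()`.  Element orientation for sense/antisense is taken
from the coding frames of the domain hits.

# Relative quantification

Amplification efficiency is fixed at 2 (no efficiency correction).  For
expression and copy number, per replicate
$\Delta Ct = Ct_\text{target} - Ct_\text{reference}$ and
$\text{fold} = 2^{-(\Delta Ct - \overline{\Delta Ct}_\text{calibrator})}$,
exponentiated per replicate and summarised as mean ± SD on the fold scale
(matching how such data are plotted); averaging $\Delta\Delta Ct$ before
exponentiation is available via `average_ddct = TRUE`.  Note that with
mean-calibrator normalisation the calibrator's own mean fold is exactly 1
precisely when its ΔCt is replicate-consistent.  ChIP enrichment is
$2^{-(Ct^{IP}_t - Ct^{in}_t)} / 2^{-(Ct^{IP}_c - Ct^{in}_c)}$, and
`normalized_mark_ratio()` forms mark/histone ratios with optional
calibrator renormalisation.  All quantities are strictly positive and
invariant under a global Ct shift to numerical precision.

# The synthetic data generator

`synth_config()` defaults describe the study conditions end to end: a 2 Mb
three-contig genome at GC 0.40; five families alternating between the two
lineages, each with 2 full-length copies (5 kb, 300 bp LTRs), 3 partials
and 3 solo-LTRs, placed non-overlapping in clustered "centromeric" windows
with ≥ 2 kb spacing; 2,000 wild-type siRNAs per transcribed element (mass
0.35 each on 23 and 24 nt, remainder uniform over 20–27; antisense
probability 0.5; 5'U target 0.75); in the mutant, no siRNAs but 2,000
sense-only 18–30 nt degradation reads per element of one designated
mobilizing family; mRNA at 5 RPKM background with Poisson bin noise
(expected 20 reads/bin) and an 8× gain over transcribed elements in the
mutant.

Choices that need stating:

* **Divergence semantics.** "Within-family divergence 0.02" is the expected
  *pairwise* divergence between two family members, so each copy is mutated
  from its ancestor at half that rate; likewise family ancestors diverge
  from their lineage cassette at half the between-family rate.  This is the
  reading under which 2% within-family divergence sits comfortably above
  the 95% family-identity threshold, as the clustering stage assumes.
* **ORF preservation.** When mutating domain-coding spans, a codon that
  would become a stop is reverted.  Discovered elements carry intact
  motifs — selection removes nonsense alleles — and the domain scanner
  rejects windows containing stops by design, so an ORF-breaking generator
  would simulate pseudogenised fragments rather than the elements the
  method targets.
* **5'U bias by start-site selection.** Reads wanting a 5'U draw their
  start from positions whose genomic base yields U on the read strand
  (never by overwriting bases), so simulated reads remain consistent with
  the genome like real mapped reads.  The realised fraction is binomial
  around the target.
* **Degradation reads** are uniform-length (18–30 nt) and sense-only with
  no sequence-context preference.  The biological description of these
  species (reverse-transcription-associated RNase H cleavage products)
  includes nucleotide-window site preferences that are *not* modelled; the
  uniform model is a stand-in sufficient for strand/size classification.
* **Determinism.** Every artifact draws from its own RNG stream
  (`seed + offset`: genome, ancestry, placement, reads per condition, mRNA
  per condition), so changing read simulation never perturbs the genome,
  and a fixed seed reproduces every output byte for byte.
* **Bundled references.** The lineage cassettes were built once by
  back-translating synthetic lineage protein consensi with uniform codon
  choice and are shipped as nucleotide FASTA, so the generator's ancestors
  and the lineage-assignment references share one frame of reference.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing error and PCR duplicates; indel
divergence between copies (substitution-only); nested/fragmented element
arrangements inside unassembled repeat arrays; transcription of solo-LTRs;
replicate-to-replicate biological variability (single tracks per condition,
as in the motivating analysis); and realistic codon usage or GC
heterogeneity.  Results on real genomes will degrade where those factors
dominate, most visibly in repeat-dense unassembled regions.

# Evaluation

With a truth set, calls are matched to planted elements at ≥ 50% reciprocal
overlap (a standard matching rule; no rule exists in the source procedure),
giving per-class precision/recall, per-edge boundary errors for full-length
calls, called-base precision, a class confusion matrix, and the adjusted
Rand index between called and planted family partitions
(`mclust::adjustedRandIndex`).  The problem sizes used by the test suite
and the acceptance script — a 0.9 Mb genome with 15 elements for module
tests, the full 2 Mb / 40-element configuration (run twice for the
determinism check) plus a 3.6 Mb / 200-element set for the weakened-bias
classifier stress test — are the package's chosen desk-scale study
conditions.

# Known limitations

The PSSM scanner is ungapped (no insert/delete states); profile HMMs would
be the natural extension.  The empirical null is permissive at
$\alpha = 10^{-3}$, which the pipeline mitigates structurally (positive-bit
rules above) rather than by tightening $\alpha$.  Copy-number claims from
the qPCR arithmetic inherit the no-efficiency-correction assumption.
Lineage labels are nearest-reference assignments on an NJ tree, not
model-based phylogenetics.  The pipeline processes one mutant/wild-type
pair; replicate handling is out of scope.
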
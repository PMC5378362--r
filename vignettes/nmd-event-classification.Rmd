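---
title: "Classifying the structural events behind nonsense-mediated decay targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the structural events behind nonsense-mediated decay targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscan)
```

## The model

Nonsense-mediated decay (NMD) removes mRNAs carrying a premature
termination codon (PTC). Under the scanning model of translation, the
ribosome dissociates at the first in-frame stop; when that stop lies well
upstream of the last exon–exon junction — operationally, more than 50
nucleotides, measured in spliced (mRNA) coordinates — the junction complex
left behind recruits the NMD machinery. nmdscan takes this *50-NT rule* as
its detection criterion and asks a second question: given that a transcript
is an NMD target (NMDT), which change in splicing created its PTC?

The package answers under a minimal-change assumption: of all events that
could have produced the target from a normal coding isoform, the smallest
one is the most probable. Concretely, the target is compared against a
single *best partner* — the coding isoform of the same gene that (i) starts
translation at the same genomic position and (ii) shares the largest
proportion of the target's exonic nucleotides. Requiring a shared start
makes the downstream frame comparison meaningful; normalising overlap by
the target's spliced length (rather than a Jaccard index, which is
available via `denominator = "jaccard"`) reads "proportion of the target
shared" literally and is the default.

### Exon groups and the frame ledger

The exons of target and partner are merged into *exon groups*: exons whose
genomic regions overlap by at least one nucleotide belong to one group,
transitively, and an exon overlapping nothing in the other transcript forms
a singleton group. Two worked examples fix the semantics: exons at
100–500 and 300–700 form one group spanning 100–700, and an exon at
2000–2500 facing partner exons at 1800–2200 and 2300–2700 forms a single
group spanning 1800–2700 (the latter is an intron retention signature: a
contiguous exon overlapping two exons of the other transcript necessarily
covers the intron between them).

Within each group the CDS nucleotides of the two transcripts are counted
and the difference accumulated 5'→3' modulo 3 — the *frame ledger*. UTR
bases count for neither side, which is what routes pure-UTR differences
away from the structural categories; a transcript compared against itself
has an identically zero ledger. The first group at which the cumulative
difference becomes non-zero is a frameshift candidate. If a downstream
group returns the sum to zero, the upstream event is *rescued* — it cannot
explain a PTC further downstream — and the scan re-initiates after the
rescue group.

Two boundary decisions deserve explanation because the field's verbal
descriptions leave them open:

* **The scan stops before the group containing the PTC.** Inside that
  group the target's CDS is truncated by the very stop we are trying to
  explain, so its CDS length disagrees with the partner's whether or not a
  frameshift occurred; the disagreement carries no frameshift information,
  and treating it as one would mislabel structurally identical stop groups
  as causal. Groups strictly upstream contain complete CDS on both sides
  and are the only place a frameshift can be read off cleanly.
* **A balanced ledger with a structural difference falls back to the
  stop-introducing event.** A PTC requires either a frameshift or a
  sequence change that physically contains (or abuts) the new stop. When no
  non-rescued frameshift exists but the pair differs structurally at or
  upstream of the PTC group, the structural difference *nearest the stop*
  is reported as causal, with `mechanism = "stop_introduction"`. This is
  the minimal-change reading of three real situations: an in-frame
  (length ≡ 0 mod 3) inserted exon whose own sequence carries an in-frame
  stop; an in-frame exon-boundary extension whose added sequence carries a
  stop; and an in-frame deletion or truncation whose new junction fuses a
  stop codon. Only when *no* structural difference exists upstream of the
  stop does the call fall through to `UTR_Diff_CDSdiff_NoFrameDiff`. The
  alternative — labelling every balanced-ledger case a UTR-driven event —
  misattributes a visible, located structural change and demonstrably
  breaks the simulation: a third of inserted exons are frame-preserving,
  and most of those long enough to be realistic contain a stop.

### The taxonomy

The causal group's membership pattern names the event: partner-only exons
are exclusions (`NMD_ex`, `multi_NMD_ex`), target-only exons inclusions
(`NMD_in`, `multi_NMD_in`); a one-vs-one pair with mismatched edges is an
alternative splice site, a one-vs-two pattern is intron retention
(`NMD_IR` when the target retains the intron, `nNMD_IR` when the partner
does). One-vs-three-or-more and two-vs-two-or-more patterns are ambiguous
superpositions (e.g. an inclusion inside a partner-retained intron) and are
reported `Complex`, as is the degenerate case of a causal group whose exons
are coordinate-identical. Identical CDS structures short-circuit to
`UTR_Diff` before any scanning. Every classified target lands in exactly
one category; targets with no start-sharing coding isoform are reported
`Unpartnered` rather than forced into the taxonomy.

Splice-site naming is a convention, not a fact of the data: nmdscan calls a
mismatch at the exon edge facing the splice *donor* (the exon's
3'/downstream edge in transcript orientation) `A5SS` and the acceptor-side
edge `A3SS`, because the sites — not the exon edges — carry the 5'/3'
labels in the splicing literature. `ss_convention = "exon_edge_is_5"`
swaps the naming for users who read the labels as exon edges; nothing else
changes.

## Detection rules and their parameters

* `distance` (default): target iff `d > threshold`, with
  `d = last_junction − stop_end` in mRNA coordinates and `threshold = 50`.
  The comparison is strict, consistent with "more than 50 nt" phrasing and
  with threshold sweeps that peak just above 50. The stop anchor is its
  *last* base (`anchor = "stop_end"`); anchoring at the first base shifts
  every distance by +2 and is exposed because published formulations do
  not fix the anchor. Single-exon transcripts have no junction and are
  never called.
* `uorf`: a complete upstream ORF — ATG with an in-frame stop, minimum two
  codons, entirely within the 5'UTR. Overlapping uORFs (stop downstream of
  the main start) deliberately do not count; the strict form is the common
  one and the permissive form collapses into calling most transcripts.
* `utr3`: spliced 3'UTR strictly longer than `utr3_min` (default 650 nt).

Codons containing `N` never match ATG or a stop. In de novo mode the main
ORF is the longest ATG-initiated reading among the three forward frames
(the assembler fixes the orientation), ties resolved to the 5'-most start.
A consequence worth knowing: a heavily truncated ORF can lose the
"longest" contest to a downstream reading, so de novo detection is
conservative — it can miss annotated targets but does not invent coding
transcripts as targets.

## The simulator and what it shows

`run_simulation()` injects exactly one alteration per artificial
transcript: random deletion of an internal coding exon, conversion of part
of a randomly chosen intron into an exon (length drawn from the empirical
internal-coding-exon length distribution, at least 1 intronic nt left on
each side so both junctions survive), or extension/abridgement of an
internal exon at its 5', 3' or both ends with equal probability (the
length change split as evenly as possible for "both", extra base to the
5' side; extensions clamped to keep 1 nt of intron, shrinks clamped to
keep the exon ≥ 1 nt). Terminal exons are off limits: altering them moves
the translation start or the annotated end and would break the
shared-start premise the classifier depends on — restoring the literal
"any coding exon" behaviour is a one-line change but produces events the
method is explicitly not designed to classify. Source transcripts are
drawn with replacement; each replicate `r` reseeds the generator at
`seed + r − 1`, so any replicate can be reproduced in isolation.

Whether a product *is* a target is decided by re-deriving its ORF from
sequence — translation from the source's start codon to the first in-frame
stop in the altered spliced mRNA — and applying the 50-NT rule. A
classification is scored correct when the category is consistent with the
injected event type (deletion → `NMD_ex`/`multi_NMD_ex`; insertion →
`NMD_in`/`multi_NMD_in`/`NMD_IR`; boundary → any splice-site class) and
the causal group's span overlaps the altered span.

The accompanying annotation generator emulates the features the method
relies on: multi-isoform protein-coding genes on both strands, genuine
ATG…stop ORFs threaded through 5–9 exons, a coding decoy isoform per gene
differing only in 3'UTR length (so partner selection has a real choice to
make), and optional NMD-target isoforms built by frame-shifting boundary
truncation with CDS re-derived by translation and checked against the
50-NT rule. 5'UTRs are generated ATG-free so the annotated start is the
true main-ORF start. The default checks run 20 replicates of 5,000
alterations on a 200-gene annotation (seed 42) — the per-replicate event
count of the original protocol with the replicate count scaled to desk
size; accuracy is insensitive to the replicate count long before 20.

What the near-perfect simulated accuracy does **not** show: real
annotations contain "coding" isoforms that are themselves NMD targets
under the 50-NT rule, and choosing such an isoform as partner is the
dominant real-world error mode of minimal-change classification. The
generator guarantees clean partners, so the simulation measures the
classifier's intrinsic correctness, not its robustness to annotation
inconsistency. Real data also bring multi-event histories, non-ATG
initiation, and PTCs from point mutations — all outside scope.

## Numerical and degenerate-input choices

* All coordinates are 1-based inclusive; any half-open arithmetic is
  internal.
* GTF `stop_codon` features are merged into the CDS on read, so a stored
  CDS always includes its stop; Ensembl-style input (which excludes the
  stop from CDS features) and already-inclusive input normalise to the
  same representation before any distance is computed.
* The Ensembl-V75 dialect (biotype in the source column) is auto-detected
  by sniffing the first 100 feature records; an explicit
  `transcript_biotype`/`transcript_type` attribute always wins.
* Partner ties break by count of identical exon boundaries, then
  lexicographically smallest transcript id — fully deterministic.
* MCC returns 0 when any denominator factor is 0; the D-value returns 0
  when both FPKM values are 0 and rejects negative input; D histograms use
  right-closed bins of width 0.2 over [−1, 1].
* The MCC threshold sweep evaluates `target iff d > t` for every integer
  `t`, including negative thresholds (stops downstream of the junction);
  transcripts with no junction or no terminal stop are never called
  positive at any threshold.
* Transcripts with exons on several chromosomes or strands are skipped and
  logged, never repaired; duplicate exon records are deduplicated with a
  warning; annotated transcripts with no CDS are excluded from detection
  denominators and classification and surface in the skip log.

## Known limitations

Pairwise comparison cannot resolve histories involving several
simultaneous events (`Complex` is a label, not an explanation). Causality
inside a complex group is not apportioned. Mutation-created PTCs are
invisible to a structure-only comparison. The A5SS≫A3SS asymmetry seen in
real classifications depends on the splice-site naming convention, which
is why it is configurable rather than hard-coded.
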
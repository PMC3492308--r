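---
title: "Intron dynamics in fungal cytochrome b genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron dynamics in fungal cytochrome b genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mitochondrial cytochrome b (cob) genes of fungi carry large (often > 1 kb)
group I introns whose presence varies wildly between even closely related
species: some genes carry six or seven, most carry none. That patchiness is
the signature of an active evolutionary process — introns are repeatedly
lost (precisely excised, most plausibly via recombination with a reverse
transcript of the spliced mRNA), occasionally gained laterally from other
lineages, and sometimes transposed to new sites within the gene. The
intron complement also matters practically: an intron interrupting codon
143 blocks the G143A substitution that confers QoI (strobilurin) fungicide
resistance, so a gain or loss at that site changes a pathogen's
evolutionary options.

`cobintron` implements the full analysis chain used to study these
dynamics: decomposing genomic/cDNA pairs into exons and introns, placing
every intron in a common (reference-gene) codon coordinate system,
clustering introns into homologue families by local-alignment statistics,
summarizing their distribution, and reconstructing loss, lateral-gain and
transposition events on a species tree. A synthetic-data generator
produces catalogues with a complete ground-truth event log, so every stage
is testable end to end without touching sequence databases.

## Coordinates: insertion points, positions, phases

All intron locations are anchored in coding coordinates. The *insertion
point* `p` counts coding nucleotides 5' of the intron (the intron sits
immediately after coding nucleotide `p`, 1-based). The interrupted codon
is `ceiling(p/3)`; the *phase* is `p mod 3` — 0 between codons, 1 after
the first base, 2 after the second. The inverse,
`p = 3(codon - 1) + (3 if phase == 0 else phase)`, is exact, and the
package enforces it as an invariant.

Positions from different genes are made comparable by aligning each
deduced protein to a designated reference gene (pairwise global alignment,
BLOSUM62, affine gaps) and reading off the aligned reference codon. A
pairwise alignment per species replaces a joint multiple alignment: it
makes every species' mapping independent of which other species happen to
be in the catalogue, at the cost of ignoring information a full MSA could
bring to ambiguous regions; a precomputed MSA can be substituted by
mapping through it externally. When a query codon faces a reference gap,
the nearest reference residue to the left is used and the assignment is
flagged (`ref_gap`) rather than silently accepted. Translation uses NCBI
table 4 (mold mitochondrial): fungal mitochondria read TGA as tryptophan,
and table 1 would produce spurious internal stops; the table is
configurable.

## Extraction and junction ambiguity

With a same-isolate gDNA/cDNA pair, exons are exact substrings of the
genomic sequence, so extraction is greedy maximal anchoring: match the
cdna left to right, and call the skipped genomic segments introns. Two
judgement calls deserve spelling out:

* **Junction ambiguity.** When the last exonic base(s) before an intron
  equal the intron's last base(s), several placements of the boundary
  yield the same spliced product. The canonical placement is the one whose
  intron ends in G with an exonic T immediately 5' — the group I splice
  consensus. A short argument shows at most one equivalent placement can
  satisfy the consensus (any non-leftmost placement forces the preceding
  exon base to equal the terminal intron base, which T ≠ G forbids), so
  the rule is deterministic; when no placement qualifies the leftmost
  intron start is taken and `placement_ambiguous` is set for review.
* **Anchoring.** The next exon after an intron is located by anchoring a
  prefix of the remaining cdna; anchors shrink from 20 to 8 nt because
  real cob exons can be as short as ~11 nt, and never below 8 nt because
  shorter anchors match spuriously across a 10 kb gene. A bounded
  backtracking search covers the rare anchor collision. Mismatch-tolerant
  extraction (`max_mismatches_per_exon > 0`) reads through isolated
  substitutions for database records of uneven quality; a full
  dynamic-programming fallback was considered and not built — budgeted
  greedy extension covers the intended use, and noisy records are better
  surfaced than silently repaired.

## Sliding introns

Database annotations of the "same" intron in different species sometimes
disagree by a few nucleotides. Introns from different genes whose
reference locations differ by fewer than 6 nt are treated as *sliding*
candidates: the normalizer looks for signed boundary shifts of at most
5 nt per intron that leave each genomic sequence untouched (bases merely
move between exon and intron annotations), restore the T…G consensus for
every shifted intron, and bring the group to a single location. The
minimal total |shift| solution is applied (ties toward the smaller
location); groups with no solution are flagged `unresolved_sliding` and
left in place. The operation is idempotent, and a shift may alter the
annotated exonic codon — that is the point: the genomic sequence, not the
annotation, is the ground truth.

## Homology and families

Pairwise intron homology follows BLASTN-era practice. HSPs come from NCBI
`blastn -task blastn` (word size 11, +2/−3, gap 5/2 — the classic
defaults) run pairwise, so E-values refer to the pairwise `m·n` search
space; for catalogue-scale work all comparisons run as one all-vs-all
search whose hits are re-scored to the pairwise search space from their
bit scores (`E = m·n·2^{−S'}`, no edge correction — deterministic and
documented, and the decision thresholds below are scale-free anyway). A
pure-R repeated Smith–Waterman engine (Karlin–Altschul λ solved
numerically; K a documented constant, 0.41 for these scores) serves where
the binary is unavailable.

HSPs are tiled greedily by descending score on the longer sequence's
axis; an HSP is accepted only if, after clipping an overlap of at most
10 nt, it overlaps no previously tiled column. Coverage is the summed
tiled length over the longer intron's length; mean identity is the
tiled-weighted `100·Σ identities / Σ aligned columns`. Greedy tiling with
zero-overlap acceptance provably returns the lexicographically best (by
descending score sequence) non-overlapping subset, which is what the test
suite checks against exhaustive enumeration.

Two introns are homologous when coverage > 0.30 and mean identity > 80%
hold — by default in *both* query/subject orientations ("strict"
reciprocity; `"any"` accepts one orientation). Requiring mutual best hits
was considered and rejected: within a 10-member family each intron has a
single best hit, so best-hit edges would fragment exactly the transitive
groups the family table displays. Families are connected components of
the homology graph; singletons are retained and marked. Family ids are
assigned by smallest member position, then name, so output is independent
of input order, and raising either threshold can only remove edges —
families never merge (a monotonicity the tests exercise).

## Event inference

* **Losses** are reconstructed per family by Dollo parsimony: one origin
  at the most recent common ancestor of the carriers, and one loss on
  each maximal carrier-free subtree below it. This is the minimal loss
  set, and it is unique; the suite verifies equality with exhaustive
  search over sampled trees up to 8 leaves.
* **Lateral gains** are flagged per member pair when the intron identity
  exceeds the species' coding-sequence identity by more than δ = 5
  percentage points *and* some species more closely related to either
  member (topologically) lacks the family. Coding identity is the
  relatedness proxy — it is always available and mirrors the comparison
  that motivates the rule; with equal intron and coding substitution
  rates, vertically inherited pairs have zero expected anomaly, making δ
  a calibrated null margin. δ is configurable and reported in the
  evidence string.
* **Transpositions** are the minority-position members of families that
  span more than one reference position; the anchor (modal) position is
  the most populated one, with deterministic tie-breaks (closest to the
  median member position, then smallest). The rule encodes the parsimony
  judgement that the derived site is the rarer one; when a transposed
  clade outnumbers the source clade the call inverts, which is a known
  and documented limitation.

When a simulation truth log is available, `recover_events()` scores each
detector. The strata are part of the design, not afterthoughts: loss
recall is computed over *identifiable* losses — the family must be
retained both in the loss branch's sibling subtree and outside its parent
clade, otherwise Dollo provably merges the event with a neighbouring loss
or absorbs it into the origin, and no presence/absence method can place
it. Transfer recall is over *visible* transfers (the recipient copy and a
copy outside the recipient clade both survive to leaves); a flagged pair
counts as correct when it joins a carrier inside a true recipient clade
with one outside it, because the donor's copy is shared vertically by the
donor's relatives. Even among visible transfers, an event occurring soon
after the donor and recipient lineages diverged is information-
theoretically indistinguishable from vertical descent — its identity
anomaly is below any fixed δ — so transfer recall has a structural
ceiling well below 1 (about 0.7 under the default conditions; the
measured flag precision is 1.0).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions for every property test:

| parameter | default | why |
|---|---|---|
| `n_taxa` | 12 | enough branches (22) for multi-event histories while keeping all-vs-all comparisons small |
| `birth_rate`, `death_rate` | 1.0, 0.3 | mildly extinction-prone birth-death; first-passage conditioning on `n_taxa` survivors, present cut just before the next event |
| `subst_rate` = `intron_subst_rate` | 0.05/site/unit | with tree depth ≈ H(12) ≈ 3, leaf-pair coding identities span ~75–99% — the breadth of a kingdom-wide gene sample, where homologue families cross taxonomic classes; equal rates make the lateral-gain anomaly a calibrated null |
| `cds_length_codons` | 393 | typical cytochrome b protein span (cdna 1182 nt with stop) |
| `intron_length_range` | 900–1800 nt | the size range of the large fungal cob introns; 6–7 families then give 8–13 kb of intronic span per gene, matching the longest reported genes |
| `gain/loss/transfer/transposition rates` | 0.15 / 0.3 / 0.1 / 0.05 per branch | loss-dominated regime reproducing the observed patchiness (most leaves carry few or no introns); no quantitative rates are published, so these are config-exposed choices, not claims |
| `n_ancestral_families` | 4 | seeds deep families whose losses are reconstructable |
| `min_exon_nt` | 12 | minimum spacing between occupied sites, i.e. the shortest internal exon; real cob exons bottom out near 11 nt |

Insertion sites are coding positions with a T, screened at generation;
those T bases and each intron's terminal G are frozen during evolution, a
stand-in for the selective constraint that maintains splice competence.
Coding sequences evolve by exact per-branch Jukes–Cantor transitions
(start/stop preserved, internal stops resampled); intron families evolve
under the same process. Events are drawn per branch as Poisson counts
with uniform times; transfers copy a contemporaneous lineage's current
sequence verbatim (the copy then diverges independently), gains introduce
novel families at free sites, losses remove a present family precisely,
and transpositions relocate a family (at most once per family per
branch). Everything is reproducible bit-for-bit from one integer seed.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no indels in exons or introns, no rate
heterogeneity or selection, no homing-endonuclease ORFs or repetitive
content inside introns, no site-preference sequence specificity beyond
the T…G consensus, no annotation noise (the mismatch-tolerant extraction
path is exercised with constructed cases instead). Real catalogues also
mix sequences of uneven quality and partial genes, which enter the
summaries as "unknown" intron counts but are excluded from position-based
analyses.

## Numerical and degenerate-input choices

* Insertion-point arithmetic is integer-exact; the `p` ↔ (codon, phase)
  invariant is tested across 10^5 points.
* Rounding in the frequency tables is half-up to 2 decimals, matching the
  printed-survey convention (69/465 → 14.84, 92/3276 → 2.81); R's
  banker's rounding is deliberately not used.
* "Fewer than 6 nucleotides" for sliding candidates is a strict `< 6` on
  the nucleotide-scale distance; shifts are bounded at |5|.
* Ambiguity codes (N etc.) are accepted on input and count as mismatches
  in all comparisons; they are never silently converted.
* An empty HSP list tiles to coverage 0 and identity 0; single-member
  families are retained; a single-carrier family has its origin at the
  carrier tip and no losses; intron-free genes appear in summaries with
  zero counts.
* Introns whose position cannot be determined (`NA` reference codon) are
  retained in the catalogue but excluded from position-based analyses and
  counted separately.

## Problem sizes

The test suite simulates hundreds of 12-species catalogues (~500 genes
for the extractor round trip, 100 catalogues for event-recovery scoring,
10^4 sampled cases for the Dollo-vs-enumeration check), and the analysis
scripts run one default catalogue end to end; these sizes were chosen so
the whole suite completes comfortably on a laptop while keeping
Monte-Carlo error well inside the asserted margins.

## Known limitations

* Lateral-transfer recall is structurally bounded (see above); the
  reported precision/recall are properties of the rule under the stated
  conditions, not of the biology.
* The minority-position transposition rule inverts when the derived clade
  outnumbers the source clade.
* Dollo undercounts losses when sibling lineages lose a family
  independently; the event-level scoring makes this visible instead of
  hiding it.
* The GenBank reader handles single-gene flat files with annotated CDS
  exon coordinates (`join(...)`, `complement(...)`); records whose CDS
  lacks exon sub-coordinates fall back to being intronless or need a
  user-supplied cDNA via the FASTA-pair route.
* E-values from the batched all-vs-all search are re-scored without
  BLAST's effective-length edge correction; decisions rest on coverage
  and identity, which do not depend on the E-value scale.
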
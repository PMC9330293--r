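---
title: "Template-based antibody assembly: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based antibody assembly: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abassembly)
```

## The assembly model

Bottom-up proteomics *de novo* sequencing produces peptide reads of 5–40
amino acids with two quality signals: a per-residue local confidence and a
global confidence (PEAKS' ALC, 0–100%), plus optionally an MS1 peak area.
Reads this short cannot be assembled by overlap alone, but antibody
variable domains are derived from germline V/(D)/J gene segments with
somatic hypermutation rates of only 1–10%, so germline amino-acid templates
are close enough scaffolds to anchor every read. The package's model is
therefore a two-pass template assembly:

* **Pass 1** places reads on germline segment templates by local alignment
  and calls a weighted consensus per template.
* **Recombination** concatenates the top-scoring V/J/C consensus into a
  candidate full chain, reconstructing the CDR(H)3 junction — which no
  germline template covers — from reads that overhang the V and J ends.
* **Pass 2** re-places all reads on the recombined chain(s) and calls the
  final consensus. Non-selected germline templates can join this pass as
  decoys so that background reads (polyclonal contamination, second
  hybridoma chains) are absorbed instead of corrupting the target
  consensus.

Assumptions worth stating: substitution-type disagreements between reads
and templates dominate (indels in de novo reads are rare); reads are
independent evidence (duplicate spectra accumulate weight, which is how
frequency enters the consensus — there is no separate frequency factor);
and heavy/light chain pairing is outside the model's reach.

## Scoring alphabet

The default alphabet is BLOSUM62 over the 20 residues plus `X`, with two
mass-spectrometry-specific changes:

* **I/L is one residue class.** Isoleucine and leucine are isobaric and
  indistinguishable in standard fragmentation, so `score(I,L) =
  score(I,I) = score(L,L) = 4`, and against every third residue both take
  the more favorable of their two BLOSUM62 scores. The second part is what
  makes alignment scores invariant to the arbitrary I-vs-L choice a de
  novo engine makes; with plain BLOSUM62 rows, `I` vs `V` scores 3 but `L`
  vs `V` scores 1, and the same spectrum could match differently depending
  on which letter the engine printed.
* **`X` scores 0 against everything** — it is the placeholder used for
  junction extension, not an observation.

Gaps are affine: 12 to open (first gapped residue), 1 to extend. The gap
penalties are deliberately stiff relative to BLOSUM62 because the dominant
read error mode is substitution; a custom matrix can be supplied as a TSV
(`read_alphabet_tsv()`).

## Matching cutoff and normalization

A read matches a template when `raw_score / sqrt(read length) >= cutoff`
(default 8). Normalizing by the square root of the *whole* read length
makes one cutoff meaningful across the 5–40 aa range, and — importantly —
prevents an incidental few-residue anchor inside a long read from passing:
a single tryptophan pair scores 11, which would beat any practical cutoff
if the divisor were the aligned span only. A configuration switch
(`normalize = "template_length"`) divides by the square root of the
template length instead, which penalizes short spurious matches even
harder but requires retuning the cutoff per template class.

Placement and uniqueness are computed per template pool, i.e. per (chain
group, segment class): V, J and C libraries are separate databases, so a
junction-spanning read can legitimately be unique on a V template and on a
J template at the same time. Pooling classes together starves the short J
segments (junction reads almost always score higher on V) and breaks the
tip/branch-point semantics of the per-class cladograms.

## Consensus weighting

Each aligned read residue deposits

`weight = local_conf × global_conf × w(area)`,
`w(area) = clamp(2 − 1/log10(area), 1, 2)`

into its template column; absent areas and areas ≤ 10 (where the formula
leaves the band) contribute `w = 1`, so reads without abundance data count
fully once. Multiplication makes a zero-confidence residue inert.
Numerical details that the field's tools usually leave implicit:

* **Ties** at a column prefer the template residue, then the
  lexicographically smallest candidate — a deterministic template prior.
* **Deletions**: reads aligned across a template column with a gap deposit
  weight on a dedicated deletion symbol (scaled by the confidences of the
  flanking read residues); a column won by the deletion symbol is omitted
  from the consensus and logged.
* **Insertions** between columns accumulate per inserted string; an
  insertion is emitted only when its weight exceeds half the mean total
  weight of the two flanking columns. This threshold is plumbing, chosen
  so that a majority of covering reads must carry the insertion.
* **I/L resolution**: where the consensus says L, the support is purely
  I/L, and the template says I, the consensus becomes I and the position
  is recorded. Covered columns whose support includes any other residue
  are never touched.

## CDRH3 junction reconstruction

The V consensus is extended C-terminally, and the J consensus
N-terminally, with 20 `X` positions. Reads are re-matched against the
extended templates; an alignment that reaches the segment boundary
continues diagonally through the zero-scoring `X` columns, so unaligned
read tails become overhang evidence. The `X`-region consensus is kept up
to the first uncovered column. Two guards keep junk out of the overhang:

* Only reads whose best first-pass placement is the selected V (resp. J)
  template may contribute. Without this, any read with a coincidental
  boundary-anchored match drags its unrelated tail into the placeholder
  region.
* The overlap between the two extended sequences is searched over all
  offsets in a window of at most 40 residues, but a candidate overlap must
  touch read-derived overhang residues on at least one side and can never
  exceed `v_overhang + j_overhang` — template-only overlaps are
  coincidental homology, not junction evidence. The search includes the
  containment case (the whole extended J inside the extended V), which is
  the normal geometry for light chains, where a 20-residue V overhang runs
  past the end of the short J; V-side residues past the J end are trimmed
  on merge since the next segment's consensus follows anyway.

If no admissible overlap scores positively, the sequences are concatenated
and a single gap is recorded (`gap_inserted`). On conflicting residues
inside the overlap the V side wins: its overhang is anchored by the
conserved cysteine region and, in practice, has the deeper coverage.

With N > 1 selected templates per class, the recombined set is the
cartesian product of the selections; the second pass reports each
recombined template's consensus directly, without re-ranking.

## The synthetic study conditions

The generator defaults define the conditions every test and the acceptance
script run under; they are chosen to emulate a realistic desk-scale
antibody experiment:

| parameter | default | rationale |
|---|---|---|
| V/J/C per chain | 20 / 5 / 3 | order of magnitude of a nonredundant germline library |
| segment lengths | 100 / 16 / 100 aa | V and J match germline domains; C is a scaled-down constant region |
| V, C family divergence | 0.12 from a family ancestor | sibling V genes within a family are homologous but distinct |
| J family divergence | 0.30 | germline J genes are short and mutually distinct (human IGHJ genes differ at roughly 40% of positions) |
| SHM rate | 0.05, i.i.d. over the variable region | middle of the observed 1–10% range |
| junction insert | 3–10 residues (heavy), 0 (light) | D region plus non-templated additions |
| proteases | trypsin, chymotrypsin, gluC, aspN; 1 missed cleavage | a typical multi-protease design |
| read lengths | 5–40 aa | observed LC-MS/MS de novo read range |
| read error rate | 0.01 substitutions/residue, low local confidence at errors | dominant de novo error mode |
| depth | 10 reads/position | routine coverage |
| MS1 areas | log-normal, meanlog log(1e6), sdlog 1 | typical peak-area spread |
| I→L collapse | on | de novo engines emit L for the isobaric pair |

What the generator does **not** emulate: CDR-focused hypermutation bias
(available as an option but off by default, since uniform SHM keeps the
substitution-count statistics testable), indel read errors (toggle
available), chimeric or semi-tryptic peptides, retention-time or charge
effects, and deamidation chemistry. Passing tests therefore demonstrate
the assembly logic under realistic homology, coverage and noise — not
robustness to every artifact of real LC-MS/MS data.

Problem sizes in the test-suite and acceptance script — 20 simulated
repertoires for end-to-end recovery, 500 random pairs against the
exhaustive alignment oracle, 50 consensus round-trips, 3 background
spike-in scenarios — keep a full run within a few minutes on one CPU while
holding the statistical properties (binomial SHM counts, 3-sigma depth
bands) testable.

## Determinism

All generators are deterministic under their seed; ties in alignment
traceback (diagonal over delete over insert), in consensus calls, in
ranking (score, then unique score, then id) and in cladogram agglomeration
(smallest member id) are broken by fixed rules, so identical inputs
reproduce byte-identical TSV/JSON/FASTA/Newick artifacts. The HTML report
contains no timestamps.

## Known limitations

* The junction is only as good as its overhang coverage: with fewer than
  ~5 residues of true overlap the merge degrades to a gapped concatenation
  (flagged `gap_inserted`), and junction residues cannot be I/L-resolved
  because no germline template covers them.
* Uniform SHM plus substitution-only read errors make consensus recovery
  slightly easier than on real data, where errors cluster in
  low-fragmentation regions.
* Decoy exclusion is all-or-nothing per read (a read strictly best on a
  decoy is dropped); fractional reassignment is not attempted.
* Heavy–light pairing, spectrum-level rescoring and D-segment template
  libraries are out of scope.
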
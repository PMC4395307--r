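---
title: "Comparative mitogenome organization and gene-tree typing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome organization and gene-tree typing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorg)
```

# Scope and model

`mitorg` re-implements, as a tested pipeline, the comparative organization
analysis applied to the eight published anemonefish (Pomacentridae:
Amphiprioninae) mitogenomes and their phylogenetic congruence summary. Four
analysis stages sit over a common set of containers:

1. **Genome model** — parse annotated circular mitogenomes (GenBank flat
   files) and build the comparative gene table: per-gene nucleotide size,
   encoded protein length, start codon, stop-codon class (including the
   incomplete `T-`/`TA-` classes), anticodon, signed intergenic spacer and
   strand, plus a rotation-invariant gene-order signature.
2. **Composition statistics** — per-sequence base compositions, cross-genome
   Mean±SD summaries, a one-way ANOVA for compositional (anti-G) bias, and
   pairwise identities over alignments.
3. **Control-region annotation** — dissection of the D-loop into the
   termination-associated sequence (TAS), central conserved domain (CCD) and
   conserved-sequence-block (CSB) regions using a built-in consensus motif
   library, TAS/cTAS hairpin detection, and a tandem-repeat detector that
   reports fractional copy numbers.
4. **Tree-form typing** — parsing of bracketed tree-form strings and Newick,
   clade algebra, and classification of each gene tree into topology types
   I–IV (or non-monophyletic) by the position of *Premnas biaculeatus*.

A fifth, first-class module generates seeded synthetic mitogenomes, D-loops,
alignments and trees with complete ground-truth bookkeeping; it is how the
analysis stages are validated in the absence of downloadable accessions.

# Genome model

## Coordinates and strands

Coordinates are 1-based inclusive in the GenBank dialect. A feature that
wraps the circle's origin carries two intervals (from a `join()` location);
all other arithmetic is modular on `[1, length]`. The strand written in
`ORIGIN` is the heavy (H) strand; `complement()` features are light-strand
(L) encoded and are reverse-complemented before any codon analysis. In the
canonical vertebrate arrangement only ND6 and eight tRNAs are L-strand.

## Stop-codon classes and protein lengths

Vertebrate mitochondrial CDSs terminate either with a complete codon (TAA,
TAG, or the AGA seen in ND5) or with an incomplete stop of one (`T-`) or two
(`TA-`) bases that is completed to UAA by post-transcriptional
polyadenylation. The classifier reads the class jointly from the CDS length
modulo 3 and the terminal base(s); `protein_length()` then applies one
uniform rule:

$$\mathrm{aa} = \frac{\mathrm{nt} - \ell_{\mathrm{stop}}}{3},\qquad
\ell_{\mathrm{stop}} = \begin{cases}3 & \text{complete stop}\\ 1 & T\text{-}\\ 2 & TA\text{-}\end{cases}$$

Published comparative tables for this genome set are consistent with this
rule for eleven of the thirteen protein-coding genes (e.g. ND1 975 nt → 324
aa; Cytb 1,141 nt → 380 aa; ATP6 683 nt → 227 aa). The printed counts for
COI (1,566 nt / 522 aa) and ND5 (1,866 nt / 622 aa) are one residue larger
than the rule gives; since no counting rule reproduces all rows at once, the
package applies the uniform rule everywhere and documents the two
discrepant genes rather than special-casing them
(`aggregate_gene_tables(..., reference_aa=)` reports such discrepancies).

## Intergenic spacers

Comparative gene tables print, on each gene's row, the signed spacer between
that gene and its *predecessor* on the circle; negative values are
overlapping nucleotides. This is the only reading consistent with the
canonical vertebrate overlaps (ND4L/ND4 −7, tRNA-Ile/tRNA-Gln −1,
tRNA-Gln/tRNA-Met −1, ATP8/ATP6 −10, ND5/ND6 −5) and it is the convention
`gene_table()` uses. The `intergenic_spacing()` operation reports the
complementary view (spacer from each feature to its successor, circular at
the wrap), and the two satisfy a conservation identity on a gap/overlap
complete annotation: feature sizes plus signed spacers sum to the genome
length.

# Composition statistics

Percentages are computed over unambiguous A/C/G/T counts; ambiguity codes
and gaps are excluded from the denominator and reported. Summaries use the
arithmetic mean and the sample SD (n−1); all rounding for report tables is
**half-up** at the target precision (2 decimals for percentages, integer
bp for sizes) because half-to-even does not reproduce published cells such
as a D-loop A+T mean of 66.39 from an exact mean of 66.385. Internal math is
kept at full precision.

Recomputing a published Mean±SD row from printed per-species values can
land exactly on a rounding boundary when the original row was derived from
unrounded underlying compositions; for the whole-genome table this happens
in two of twelve cells (T mean 25.715, G SD 0.35498). The package asserts
exact agreement for all other cells and one-unit-in-the-last-place agreement
for boundary cells.

The compositional-bias test is a one-way ANOVA with **bases as groups**
(A%, T%, G%, C%) and genomes as observations, with the verdict "anti-G" when
the group means differ at the 0.05 level and G has the lowest mean. The
grouping deserves a note: the source description ("sequence variability of
different regions") is ambiguous, and grouping by base is the only reading
under which a base-bias verdict is a possible outcome; grouping by genome is
exposed as an option (`grouping = "genome"`). The test's size is checked by
simulation (null rejection rate ≈ 0.05 over 1,000 replicates).

Pairwise identity uses pairwise (not listwise) gap deletion: a pair's
denominator is the number of columns where neither sequence has `-`. Other
tools differ here (some alignment viewers delete gap columns listwise);
with gap-free inputs all conventions coincide.

# Control-region annotation

## Consensus motifs with gapped spacers

The motif library carries the TAS core variants (TACAT / TAGCAT, with cTAS
ATGTA) and nine conserved blocks: CSB-F, -E, -D, -C, -B, -A (the CCD
blocks) and CSB-1, -2, -3. Consensus strings are stored over
`{A,C,G,T,-}`; each maximal dash run of length *k* is a variable spacer
that may expand to `0..k+2` arbitrary bases. The slack of 2 absorbs the
heterogeneous typographic length of dashes in printed consensus figures
(em dashes are stored as two hyphens); both the slack and the mismatch
budget — default ⌈15% of the literal length⌉, exact matching being too
strict for cross-species consensus — are exposed as parameters.

The scanner enumerates spacer-length combinations (at most a few hundred
per motif), scores each placement by literal mismatches with vectorized
comparisons, and collapses overlapping same-motif placements to the best
score, breaking ties leftmost then shortest. Domain building uses each
motif's single best hit; secondary hits within the budget stay in the
report but do not move domain boundaries, which keeps the partition robust
to the occasional spurious budget-level hit on a ~1 kb background.

## Domain partition

The D-loop schematic is TAS < CCD < CSB along the sequence. The TAS domain
runs from position 1 through the TAS/cTAS element; the CCD spans the
CSB-F..A best hits; the CSB domain spans CSB-1..3. Exact boundaries between
elements are not defined by any published coordinate set, so the flanking
hit edges are used as a stated convention. Tandem-repeat arrays are
labelled upstream- or downstream-of-CSBs relative to the last CSB best
hit — the biological observation being that in these genomes repeats sit
downstream, unlike the ETAS-type upstream repeats of other fishes.

## Tandem repeats

`find_tandem_repeats()` is a deliberately small seed-and-extend
approximation in the spirit of Tandem Repeats Finder (not a clone): exact
full-unit matches of the period-shifted sequence seed candidate arrays;
extension maximizes a score (+1 match, −(1−f)/f mismatch, so the
break-even mismatch density equals the budget f = 20%) with an X-drop
cutoff, and the array is trimmed to the maximum-score endpoints. Copy
number is span/period reported to one decimal, so partial terminal units
appear as fractional copies (5.5, 6.5, 3.5). Defaults: minimum period 10,
minimum 2.0 copies. Overlapping calls are canonicalized longest-span
first, then smallest period. An exhaustive exact-match oracle
(`tandem_repeat_oracle()`, quadratic, for sequences ≤ 200 bp and periods
≤ 12) shares only this canonicalization and is used as the independent
check in the tests.

Published copy numbers for this genome set (5.5 / 6.5 / 3.5 and four
genomes without arrays) cannot be desk-verified without the deposited
sequences, because the repeat units themselves are not printed; recovery is
therefore validated on synthetic data carrying that copy-number spectrum.

# Tree-form typing

## Parsing

Published tree-form strings use `(`, `[`, `{` interchangeably as nesting
decoration, omit commas between adjacent bracket groups, write a taxon
after a closing bracket as a sibling of that group, and abbreviate
`1~5` for five sibling leaves; singleton groups collapse to their child.
The parser normalizes all of this while preserving written child order.
Strings ending in `;` or containing `:` are handled as Newick through ape
(branch lengths are ignored for typing). One published string (the
Cytb+12S tree) is bracket-unbalanced in print — one surplus opener — and is
stored in `anemonefish_tree_forms()` with the balanced repair consistent
with its published type, flagged `repaired = TRUE`; the parser itself
rejects unbalanced input with a position.

## Classification

With taxa 1–8 the anemonefishes (8 = *P. biaculeatus*, 6–7 the *percula*
complex), 9 *Abudefduf vaigiensis* and 10 the outgroup *Chaetodon auripes*,
let A be the smallest clade containing 1–8 after rooting on 10. The
decision cascade is: **NM** if A contains extra taxa; **I** if {6,7,8} and
{6,7} are clades; **IV** if {1,2,3,4,5,8} is a clade, or A splits in two as
{8} against {1..7} (both shapes occur among published type-IV trees);
**II/III** if A is a polytomy with singleton child {8} — II when 8 is the
first-written child, III otherwise; **OTHER** else. The II/III split is a
presentation-level distinction (the polytomies are isomorphic); honoring
written order is documented, and a tree with 8 written last maps to III.
The classifier reproduces all 19 published type assignments
(9×I, 2×II, 2×III, 5×IV, ATP8 non-monophyletic).

## Distance plumbing

p-distances (proportion of differing non-gap columns, pairwise deletion)
and neighbor joining are pipeline plumbing, not contributions: NJ delegates
to `ape::nj` with outgroup rooting via `ape::root`. Tests verify recovery
of the generating topology on every 4- and 5-taxon additive matrix against
an independent exhaustive least-squares topology enumeration, and a
sequence-level end-to-end run (type-I generating tree, per-branch
substitution rate 0.03, 12 kb) is typed I by the classifier.

# Synthetic data: what it emulates and what it does not

The generator's defaults are the study conditions of the eight-genome set:

* canonical vertebrate gene order with the published strand assignments;
* gene lengths fixed at, or drawn within, the published ranges
  (e.g. 12S rRNA 948–951 bp, ND5 1,866 or 1,869 nt — the two observed
  states of the 3-nt length polymorphism);
* the published signed spacers, including the real overlaps (−10 at
  ATP8/ATP6, −7 at ND4L/ND4), which exercise the overlap arithmetic; start
  codons and stop classes drawn from the published per-gene options
  (ATP6 from GTG/ATG/CTG; incomplete stops planted with the matching
  length mod 3);
* H-strand base frequencies at the published means
  (A .293, T .257, G .158, C .292), with an AT-rich D-loop background
  (A .36, T .31) reflecting the elevated control-region A+T;
* D-loops carrying a TAS/cTAS hairpin, all nine conserved blocks in
  schematic order (each consensus realized with recorded spacer-gap
  choices) and optional tandem arrays with the published copy-number
  spectrum (5.5/6.5/3.5, or none), placed downstream of the CSBs; a 30 bp
  unit is used as a "short fragment, simply repeated" default since no
  unit length is published.

Two deliberate non-realisms: substitution simulation is a uniform
per-branch, per-site replacement process with no rate heterogeneity and no
indels (signal strength, not realism, is the goal), and CDS bodies are
random sequence apart from their codon constraints (no codon structure, no
selection). Passing tests therefore demonstrate correctness of the
arithmetic, scanning and typing machinery under the published structural
conditions — not performance on diverged real sequence.

One numerical subtlety: a realized consensus instance can admit several
equivalent minimal-mismatch placements (a gap fill that happens to match a
segment boundary shifts the reported span). The generator therefore fills
spacer gaps avoiding the following segment's first base, plants a guard
base run before short leading segments, and finally *verifies its own
output* — every planted element must be recovered at its recorded
coordinates by the package's annotator, else filler is redrawn (bounded at
25 attempts; in practice 1–2 suffice). The same self-consistency rule
applies to `sample_tree_of_type()`. Everything is deterministic per seed:
one global RNG stream is seeded once per generator call.

# Problem sizes used in the checks

The shipped checks run at desk scale: 50 seeded D-loops (~1 kb each) for
element recovery, 100 sampled trees per topology type, 1,000 null
replicates for the ANOVA size, 30 planted-array sequences of ≤ 200 bp for
the tandem-repeat oracle, all 18 four/five-taxon topologies for NJ, and
12 kb alignments for the end-to-end typing run. These sizes give
Monte-Carlo standard errors comfortably inside the asserted tolerances
(binomial 3-SD bands for rates; 3-SD bands for closed-form expectations).

# Known limitations

* No de novo annotation: gene calls are taken from the input feature table;
  there is no ORF discovery and no tRNA secondary-structure prediction.
* The motif library is the anemonefish consensus; applying it across
  distant taxa would need re-derived consensus strings (supported via
  user-supplied patterns, not attempted here).
* The tandem-repeat detector's mismatch model is per-base against the
  period-shifted self, not a unit-consensus alignment; highly diverged
  arrays that TRF would chain together may be split or missed.
* Pairwise identity and p-distance assume pre-aligned input; no alignment
  is constructed.
* Bayesian/ML tree inference, model selection and topology tests are out of
  scope; trees are consumed as strings or built by NJ plumbing only.
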
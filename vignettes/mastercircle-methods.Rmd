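---
title: "Assembling and analysing circular organellar genomes with mastercircle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and analysing circular organellar genomes with mastercircle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastercircle)
```

## Scope and model

`mastercircle` is a desk-scale re-implementation of the computational
pipeline used to assemble and analyse plant organellar genomes from short
Illumina reads: the chloroplast genome (~150 kb, quadripartite, with a
large inverted repeat) and the mitochondrial "master circle" (200-500 kb,
carrying multiple large direct and inverted repeat pairs that drive
intramolecular recombination into subcircles and isomeric circles).
Every stage is exercised on synthetic circular genomes generated in-repo,
with complete truth tables; the package makes no network access and does
not process the original sequencing archives.

The pipeline stages, one module each:

1. **Read preparation** (`trim_and_cut`): long reads are trimmed and cut
   into dense overlapping short fragments for a fixed-readlength
   assembler.
2. **Assembly** (`build_overlap_graph`, `walk_contigs`, `scaffold_pairs`,
   `circularize`, `polish`, driver `assemble_circle`): exact-overlap
   graph assembly with paired-read repeat resolution and circular
   closure.
3. **Assembly QC** (`coverage_track`, `midpoint_track`,
   `detect_breakpoints`, `at_rich_scan`): coverage and insert-midpoint
   diagnostics; AT-rich low-coverage origin-of-replication candidates.
4. **Repeat structure** (`find_repeats`, `repeat_fraction`,
   `recombination_products`, `gene_density`, `upstream_motif_scan`):
   repeat inventory and the master-circle recombination predictions.
5. **Divergence** (`global_align`, `percent_identity`,
   `gene_divergence`, `summarize_divergence`): per-gene divergence as
   100 minus pairwise percent identity.
6. **Editing and expression** (`apply_edits`, `codon_usage`,
   `confirm_edits`, `rpkm`, `flag_fold_change`): C-to-U RNA editing
   accounting, pileup confirmation, and descriptive expression flags.

## The offset-overlap assembler

Two reads of the common working length $\ell$ are joined by an edge when
their *offset* — the total length of their non-overlapping parts — is at
most a maximum; the implied overlap of $\ell - d$ characters must match
exactly. Two maxima matter:

* the **naive offset** (default 4 bp) bounds edges used to seed contig
  walks;
* the **extension offset** (default 12 bp, always $\geq$ naive and
  $<\ell$) bounds the edge set consulted where a walk would otherwise
  end.

Reads are deduplicated under a canonical representation (the
lexicographically smaller of read and reverse complement) with
multiplicity counts, halving the graph; strand is tracked on edges. All
tie-breaks are lexicographic, so identical inputs give byte-identical
output.

**Continuation rule.** A walk continues from a node to its minimal-offset
successor only when *all* out-edges up to the extension offset agree on a
single genomic continuation: each edge's implied extension string (the
last $d$ characters of its target) must be a prefix of the longest one,
and symmetrically for the successor's in-edges. A simple
"unique-minimal-edge" test is not robust at repeat boundaries: read
starts are approximately Poisson along the genome, so the boundary window
of one repeat copy is occasionally unsampled, which would make a genuine
junction look unambiguous and let the walk produce a chimeric contig.
Requiring agreement of the whole consulted edge set flags a junction as
soon as *any* edge within the extension offset disagrees; the probability
that one side of a junction contributes no edge at all within 12 bp is
$e^{-12\lambda}$ (with $\lambda$ the per-position read-start rate,
$\approx 1.4$ at 50x coverage of 36 bp reads), which is negligible at the
scales used here.

**Error handling.** Overlaps are exact; sequencing error is handled
downstream by depth, not in the graph. `walk_contigs(min_count =)`
removes low-multiplicity nodes before walking, and `polish` corrects
residual single-base and 1 bp indel errors by pileup majority: reads are
re-anchored with exact seeds at both ends, each disagreement is
classified as substitution / spurious reference base / missing reference
base from the anchor-implied length difference, and an edit is applied
where the alternative is supported by at least 80% of at least 5
informatively covering reads (both defaults configurable). "Informatively
covering" counts read spans shrunk by one base at each end: a read that
merely abuts a breakpoint — e.g. ends level with an indel inside a short
repeated context and therefore matches either allele — carries no
information about it and must not dilute the supporting fraction. Polishing
iterates to a fixpoint, at most 3 rounds, and the edit count is
non-increasing.

**Repeat resolution.** Contig walks stop at the flanks of any exact
repeat longer than the read; the repeat interior becomes its own contig.
Read pairs whose mates land on two different contigs vote for ordered,
oriented adjacencies with implied gaps; links need at least `min_links`
(default 5) concordant pairs, conflicts are resolved by majority, and gap
estimates are median implied gaps. Only contigs at least one insert mean
long form the ordering backbone; the junction between consecutive
backbone contigs is then re-spliced exactly by following overlap-graph
edges through the short (repeat) contigs, which may be re-used. Finally,
if the two ends of the laid-out sequence share an exact terminal overlap
of at least $\ell$ minus the extension offset, the molecule is closed
into a circle and rotated to canonical form (the lexicographically least
rotation over both strands), giving a unique representative up to
rotation and strand. This reconstruction is exact whenever every repeat
is shorter than (insert mean $-\ 2\ell$), i.e. whenever some pairs span
each repeat with both mates anchored in unique sequence.

## Synthetic data: what it emulates and what it does not

`generate_genome` plants exact repeat pairs (direct or inverted), an
AT-rich origin window (written at exact composition so the realised AT
fraction honours the request), and CDS/tRNA/rRNA gene bodies (CDS are
ATG + stop-free codons + stop) into an i.i.d. background at a requested
GC. Chance occurrences of the GGAGG ribosome-binding motif are scrubbed
from gene upstream windows before the requested motifs are planted, so
the motif truth table is exact. `simulate_read_library` provides the
three historical library designs as presets — 36 bp paired-end with
~390 bp inserts, 75 bp mate-pair with ~3 kb inserts plus a minor ~220 bp
FR "shadow" component (default fraction 0.1; the source protocol reports
the shadow's presence but not its weight), and 100 bp paired-end with
~350 bp inserts — with insert standard deviations defaulting to 10% of
the mean, FR orientation for paired-end and RF for mate-pair chemistry,
i.i.d. substitution errors, and constant qualities (no pipeline stage is
quality-aware). `simulate_edited_transcripts` draws each sequenced
fragment from an independent transcript copy carrying each edit site
with the requested efficiency.

The generator emulates uniform circular sampling, Gaussian insert sizes
and exact planted repeats. It does **not** emulate GC-dependent coverage
bias, chimeric fragments, adapter read-through, quality-dependent errors,
heteroplasmy, or nuclear-organellar transfer contamination. Passing the
end-to-end tests therefore demonstrates algorithmic correctness under the
stated sampling model, not robustness to every artefact of real
libraries; the hit-table filter and SAM interoperability exist precisely
so real-data contamination screens can be done with external tools.

## Benchmark conditions

The end-to-end property ("assembly reproduces the source circle exactly
up to rotation and strand") is checked on 20 randomized genomes, lengths
uniform on 20-100 kb at mitochondrial-like GC 0.45, each carrying two
repeat pairs of 100-250 bp (mixed direct/inverted, placed at least 2 kb
apart), sequenced error-free as 36 bp FR pairs with 390 +/- 39 bp inserts
at 50x coverage. The repeat lengths sit deliberately between the read
length (36 bp, so repeats do break the graph) and the pair span
(390 - 72 bp, so paired reads can resolve them) — the regime the method
is for. 50x is the depth at which per-window sampling gaps become
irrelevant (see the continuation rule above); the full 20-genome run
takes about 3-4 minutes on one CPU. Polishing recovery is measured on
100 planted lesions (substitutions and 1 bp indels, spaced >= 200 bp) at
50x; edit-site recovery on simulated transcripts at efficiency 0.8,
depth 50, error rate 0.

## Statistics and conventions

* **Coordinates** are 1-based inclusive in every file and exported table;
  0-based arithmetic is confined to function internals. Circular
  positions wrap modulo the length; features crossing the origin are
  written to GFF3 as two parts sharing an attribute.
* **Percent identity** counts columns whose two symbols are identical
  (gap columns never count) over all columns, including terminal gap
  columns (configurable); divergence is 100 minus PID, two decimals.
  "Synonymous" divergence is the nucleotide-level statistic,
  "non-synonymous" the amino-acid-level one; no codon-model dN/dS is
  computed. The default aligner scoring is match +1, mismatch -1, gap
  open -5, gap extend -1 (a gap of length $g$ costs $5 + g$); externally
  produced alignments are accepted verbatim by `percent_identity`.
  Summaries average genes within a species pair first, then pairs, each
  rounded to two decimals; fold ratios divide the rounded means.
* **Repeat fraction** is $100 \times \sum 2 \times \text{copy length} /
  L$ with overlapping repeat copies deliberately double-counted — the
  inventory convention under which the published mitochondrial
  inventories reproduce exactly.
* **Subcircle sizes** are measured start-of-copy to start-of-copy, the
  only convention under which the two subcircles of a direct pair sum to
  the parent length; each subcircle retains exactly one repeat copy, and
  repeat pairs wholly inside a subcircle annotate it with further
  isoforms (inverted) or child subcircles (direct).
* **Gene density** is the per-class base-span union over the genome
  length; genes duplicated on repeat copies occupy distinct spans and
  both count. Whether introns should count toward "protein-coding"
  content is not decidable from published figures alone; densities here
  are computed over whatever spans the feature table provides.
* **ABR** (allele balance ratio) is edited reads over total covering
  reads at a site — the only reading under which a 0.40 pass threshold is
  coherent; the confirmation filter is ABR >= 0.40 and coverage >= 3,
  both inclusive.
* **Fold-change flags** use max/min >= 2.5 (inclusive); the 0.01 RPKM
  pseudocount replaces the denominator only when it is zero, so the
  exact-2.5 boundary case flags. No statistical testing is attempted:
  the source expression datasets had no biological replication, so only
  descriptive flags are meaningful.
* **Hit filters** ("minimum alignment length 60/30") are inclusive at
  the boundary, the conventional reading of "minimum".

## Numerical and degenerate cases

Canonical rotation uses a candidate-refinement scan over both strands;
ties between a rotation and its reverse complement resolve to the
lexicographically smaller string. An all-AT genome makes every window of
the origin scan AT-qualified, so ranking falls through to coverage. A
zero-length alignment, an all-N GC query, a zero gene length in RPKM and
a non-C edit site are errors, not silent results. `circularize` without a
terminal overlap returns the input unchanged, linear, with a warning.
Repeat discovery seeds 20-mers over the doubled genome (so
origin-spanning repeats are ordinary runs) and de-duplicates pairs
modulo the genome length with circular containment suppression; with the
default `min_identity = 100` reported pairs are maximal exact repeats,
which on random backgrounds may extend a few chance bases beyond a
planted repeat.

## Known limitations

* The assembler requires a uniform working read length (enforce with
  `trim_and_cut`); offset and overlap are then interchangeable.
* Exact-overlap assembly tolerates sequencing error only through depth
  filtering plus polishing; at high error rates a quality-aware
  error-correction step would be needed upstream.
* Repeats longer than the insert span cannot be resolved by any
  paired-read argument at these insert sizes; the assembler then returns
  the unresolved scaffold with estimated gaps rather than guessing.
* `detect_breakpoints` reports descriptive flags; the insert-deviation
  signal assumes a unimodal library (use the dominant component of a
  shadowed mate-pair library).
* Origin candidates from `at_rich_scan` are descriptive; origin
  assignment additionally needs external sequence comparison, which is
  out of scope.
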
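---
title: "Removing donor genotypes from aligned reads: method and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing donor genotypes from aligned reads: method and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bamscrub)
```

## The problem

Aligned sequencing reads (BAM files) from human donors carry the donor's
genetic variants — SNPs, short indels, and clipped-off variant sequence —
which makes the raw data re-identifiable and therefore hard to share openly,
even in functional-genomics studies where the genotype itself is of no
interest. `bamscrub` rewrites every aligned read so that its sequence is
*pure reference genome sequence* at its aligned location. Reads that cannot
be reverted (unmapped reads) are discarded. Everything that is not genetic —
5' mapping positions, splice junctions, mate-pair fields, cell barcodes,
UMIs, read groups, custom tags — is preserved as closely as possible, and
the rewrite is designed to leave no detectable "scar" that would betray
where a variant used to sit.

## The rewrite model

For each mapped record the engine resolves a *layout*: an ordered set of
reference match blocks separated by splice gaps, plus a possibly adjusted
start position. The joint rules, applied to the record's CIGAR:

* **M / = / X** segments map query to reference 1:1 and become match blocks.
  Mismatches need no geometric change; the sequence is simply replaced by
  the reference bases.
* **I (insertion)** contributes no reference span. Its query bases are
  dropped and the read is extended by the same length at the 3' end, keeping
  the 5' mapping position constant.
* **D (deletion)** folds its reference span into the current block, and the
  same number of bases is trimmed from the 3' end.
* **N (splice gap)** ends the current block and opens the next at the
  skipped coordinate; junction coordinates are preserved.
* **S / H (clips)** are replaced by reference sequence of matching length.
  A *leading* clip on a single-end record moves the start position left by
  the clip length; on a paired record the 5' position must stay fixed (it
  anchors TLEN and PNEXT), so the clip length is added at the 3' end
  instead. Trailing clips always extend the 3' end. Soft and hard leading
  clips are treated as one unit, outermost first. Bases materialized from
  hard clips get fill qualities (default `#`, Phred 2) on the side where
  they appear.
* The *net* extension/trim is applied at the rightmost reference coordinate
  of the layout, regardless of strand — the rules above are formulated in
  reference orientation, so 5' mapping positions never move for paired
  records. If a trim consumes an entire terminal exon block, that splice
  gap is removed with the block (the documented splice-removal case) and
  trimming continues into the previous block.

Read length is conserved: the output sequence length always equals the
stored input length plus any hard-clipped length. The output CIGAR contains
only M and N; the MD tag (when the input carried one) becomes the total
matched length; NM/nM become 0. Quality strings are deliberately passed
through unchanged — editing them to stay in phase with resolved indels
would itself be a detectable correction scar — so they are simply out of
phase where indels were resolved.

Records whose resolved layout would start before position 0 or extend past
the contig end are discarded (reason `out_of_range`), not truncated:
truncation would break length conservation and create a recognizable scar.
Unmapped reads are discarded by default (they cannot be reverted);
secondary and supplementary alignments are discarded by default and can be
kept with `keep_secondary`, with the caveat that multimappers cannot be
fully protected against genotype inference.

## Auxiliary-field policy

Fields describing the alignment can leak the presence of removed variation,
so besides `seq`/`cigar`/MD: NM and nM are zeroed; MC, XN, XM, XO, XG are
dropped. In `strict` mode, MAPQ is set to 255, AS and MQ to the read length
and NH to 1 (each only where already present — adding a tag that was absent
would be a scar), and HI, IH, H1, H2, OA, OC, OP, OQ, SA, SM, XA, XS are
dropped. All other tags round-trip byte-identically; this is why the
package parses SAM record text itself (a field-by-field split) rather than
going through a reader that requires tag names up front. TLEN and PNEXT are
passed through unchanged: the clip rules are designed precisely so that 5'
positions of pairs stay valid, and no mate-resolution pass is performed.

## The synthetic fixture generator

No external dataset is needed: `simulate_fixture()` builds a seeded,
self-consistent fixture — an i.i.d.-uniform random genome, a donor
haplotype with planted SNPs and 1–10 bp indels spaced at least two read
lengths apart, and aligner-faithful reads sampled uniformly along the
genome. Reads encode every rewrite case: mismatching bases at SNPs, I/D ops
at indels, one N intron in a configurable fraction of reads (with exact,
known gap coordinates, so splice-preservation assertions are exact),
adapter-style soft/hard clips, proper pairs with consistent PNEXT/TLEN/MC,
plus unmapped and secondary records. Indel breakpoints closer than 5 bp to
a read end are emitted as soft clips instead of I/D ops, mimicking aligner
end-clipping, and the generator records per read which variants it carries
in aligned versus clipped form — the ground truth the audit tests compare
against. MD and NM are computed against the reference and cross-checked in
the test suite against `samtools calmd`.

Default conditions: one contig of 100 kb, 60 SNPs + 20 insertions +
20 deletions, 2,000 paired 100 bp records with 15% spliced, 10% clipped,
1% unmapped and 1% secondary reads. These sizes give every variant multiple
chances of read coverage at roughly 2–4× depth while keeping a full
simulate–sanitize–audit cycle fast. What the generator does *not* emulate:
sequencing-error models and quality calibration, PCR duplicates, barcode
error structure, repeats/homopolymers, and real aligner idiosyncrasies —
so green tests demonstrate the correctness of the rewrite arithmetic and
the absence of residual variants under faithful CIGAR/MD semantics, not
robustness to every artifact of real aligners.

## The independent audit

`residual_audit()` is the validator: it piles up every covered position
against the reference (htslib's pileup engine, not the package's own
rewrite code), with no base- or mapping-quality threshold — the audited
claim is absolute absence, not a statistical one. Any position where a
mismatching base has read support, any deletion span (`-` rows), and any
insertion anchor (`+` rows) counts as residual non-reference evidence; the
per-read check flags a read if it has any I/D op or any mismatching base in
an M column. On raw fixtures the audit recovers exactly the planted
variants the reads carry in aligned form; after sanitization it must find
zero residual positions and zero reads with alternate alleles — the
absolute claim that the test suite and the acceptance script verify, along
with a per-record reference-identity oracle across twenty seeds.

A second, equally independent oracle backs the geometry itself: a
brute-force walker expands each CIGAR base by base into the vector of
covered reference positions and applies the clip/extension/trim rules on
that vector. The run-length engine must agree with it on the canonical
worked cases and on 10,000 randomized CIGAR programs per run.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; conversion to
  SAM's 1-based text convention happens only at the I/O boundary.
* Output is always re-sorted by coordinate (single-end leading-clip
  resolution can move positions leftward) with the reproducible key
  (contig, position, name, flag), so repeated runs are byte-identical.
* Structural validation is reimplemented in `validate_bam_structure()`:
  htslib parse round-trip, CIGAR-vs-SEQ accounting, SEQ/QUAL length
  agreement, clip placement, contig bounds, and sort order. Mate presence
  and read-group annotation are deliberately out of its scope: a sanitizer
  legitimately discards unmapped mates and adds no read groups.
* Reference N bases (and rarer IUPAC codes) are copied into reads verbatim:
  they come from the reference, not the donor, so they leak nothing, while
  substituting them would be a scar.
* `=`/`X` are treated as match/mismatch variants of M; P is dropped.
* If a record lacks MD or NM, none is added (the "if present" rule), for
  the same no-new-tags reason as above.
* Contigs present in the BAM header but absent from the reference are a
  hard error, never a pass-through: passing unmatchable sequence through
  would leak exactly the variation the tool exists to remove.

## Known limitations

* The allow-listing of specific variant positions (keeping a few known
  sites intact) is not implemented.
* Keeping secondary/supplementary alignments weakens the guarantee; the
  option exists but defaults to off.
* TLEN drift caused by mate-end changes is not repaired (by design, see
  above); downstream tools that recompute fragment ends from CIGARs will
  see slightly different 3' ends than the original alignment had.
* Behaviour for leading clips on *reverse-strand single-end* reads follows
  the reference-orientation rule; an aligner-side convention that treated
  clip resolution in read orientation would differ. The choice here keeps
  5' reference positions stable, which is the property the method promises.
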
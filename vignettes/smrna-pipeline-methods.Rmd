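---
title: "Methods: small-RNA read processing, multi-mapping-corrected RPKM, and threshold-based differential miRNA calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA quantification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrnapipe)
```

# The problem

Small-RNA sequencing of two cell populations — here endothelial
progenitor cells (EPCs) derived from umbilical cord blood (CB, condition
B) and adult peripheral blood (PB, condition A) — yields millions of
short reads in which the 18–24 nt mature miRNA insert is flanked by
ligated adapter sequence and mixed with library artefacts: poly-A
products, reads with ambiguous base calls, 5'-adapter carry-over, and
fragments of degraded mRNA. `smrnapipe` implements the complete path
from raw FASTQ to a two-condition differential miRNA table:

1. **Admission filtering.** A read is admitted when it is free of
   poly-A, contains no `N`, does not contain the 5' adapter, and ends in
   6–18 nt of 3' adapter sequence.
2. **Trimming and collapsing.** The 3'-adapter flank is trimmed and
   identical inserts are collapsed into unique *tags* with
   multiplicities.
3. **mRNA exclusion, then miRNA assignment.** Tags occurring in an exon
   database are discarded as degraded mRNA; remaining tags are matched
   against the annotated mature miRNA catalogue.
4. **Quantification.** Per-miRNA expression is the multi-mapping
   corrected RPKM (below).
5. **Differential calling.** A signed fold change and two thresholds
   decide which miRNAs differ between the conditions.

# The RPKM statistic

For each mature miRNA the pipeline computes

$$\mathrm{RPKM} = \frac{C}{L \cdot M \cdot N} \times 10^9,$$

where \(C\) is the number of reads assigned to the miRNA's genomic
region(s), \(L\) the mature length in nt, \(M\) the multi-mapping number
and \(N\) the total mapped reads in the sample. The \(10^9\) factor is
the usual per-kilobase (\(10^3\)) times per-million (\(10^6\)) scaling.

Two of these terms need interpretation, and the package fixes them as
follows:

* **M — multi-mapping number.** M is defined *per miRNA* as the number
  of distinct annotated genomic loci encoding its mature sequence, with
  each read counted once in \(C\) regardless of how many loci it could
  have come from. This is the only reading under which M is the single
  scalar the formula requires, and it matches catalogues in which a
  two-locus miRNA (e.g. miR-29b) appears as a single entry listing both
  coordinates. An alternative per-read splitting mode
  (`split_multi_hits = TRUE`), which divides a tag's count evenly across
  distinct miRNA names it matches, is available for sensitivity
  analysis; it changes \(C\), not \(M\).
* **N — library size.** Evaluating "reads mapped to the genome"
  literally requires a genome aligner, which is outside this package's
  scope. Two desk-scale policies are exposed: `"aligned"` (default)
  counts admitted reads assigned to any reference sequence (miRNA or
  excluded mRNA), and `"admitted"` counts all admitted reads including
  unalignable tags. The policy used is recorded in the quantification
  table header and the run metadata. Reads (not collapsed tags) are the
  default counting unit; `count_mode = "tags"` switches to unique tags.

RPKM is kept at full double precision internally; rounding happens only
in table serialization.

# Differential calling

With \(a\), \(b\) the RPKMs of a miRNA in conditions A and B:

* **Signed fold.** \(f = b/a\) if \(b \ge a\), else \(f = -(a/b)\); so
  \(|f| \ge 1\) always, and the sign encodes the enriched side. This
  signed-reciprocal convention (rather than log fold) is the on-disk
  convention of the published tables the package reproduces; an optional
  `log2_fold` column is available.
* **Sentinel.** When exactly one of \(a, b\) is zero the ratio is
  infinite; the finite sentinel `9.90E+307` (the largest round value
  below the double maximum) is emitted with the appropriate sign, and
  the record carries `is_sentinel = TRUE` so downstream code never
  treats it as a real ratio. A pair zero in both conditions is undefined
  (`NA`) and never called.
* **Thresholds.** A miRNA is called when
  \(\max(a, b) > 100\) (strict; applying the abundance filter to the
  *maximum* over conditions is required for rows where one condition is
  near or at zero) and \(|f| \ge 1.5\) (inclusive; the published tables'
  boundary rows sit at 1.5016 and −1.5048). Both thresholds and the
  sentinel are configurable via `diff_config()`.
* **Ranks.** Ordinal per-condition ranks (1 = highest RPKM) with
  lexicographic tie-breaks, for reporting only. Absolute rank values
  depend on the full detected-miRNA universe of a run, so they are
  checked for internal consistency, not against published rank columns
  whose universe is not available.

On the packaged transcription of the published tables (104 rows),
recomputing the fold from the printed per-condition RPKMs reproduces
every finite printed fold to below \(10^{-6}\) relative error and the
54 CB-enriched / 50 PB-enriched split exactly:

```{r verify}
v <- verify_printed_tables()
str(v[setdiff(names(v), "records")])
```

# Preprocessing rules and their knobs

The published description lists the four admission rules but not an
order, adapter sequences, or an operational poly-A definition. The
package fixes these as its own choices:

* **Rule order** poly-A → ambiguous → 5' adapter → 3' adapter, first
  failure assigns the fate. Any fixed order makes the filter report a
  partition of the input (the counts sum to `n_input`); this one tests
  the cheap sequence-content rules before the adapter scans.
* **Poly-A rule** (not operationally defined upstream): drop if the read
  has a run of ≥ 10 consecutive `A` *or* is ≥ 80% `A` overall. The two
  clauses cover both oligo-dA tails and genuinely poly-A reads; both
  thresholds are arguments.
* **5' adapter rule:** the first 8 nt of the 5' adapter occurring
  anywhere in the read (0 mismatches by default) drops it.
* **3' adapter rule:** the longest read suffix equal to a prefix of the
  3' adapter is the flank; admission requires 6 ≤ flank ≤ 18 and a
  trimmed insert of 15–30 nt (mature miRNAs are 18–24 nt; the window
  leaves slack for length variants). Matching is exact by default — the
  most reproducible choice when the original stringency is unknown — with
  a mismatch knob for sensitivity studies.
* **Adapters are mandatory configuration.** `default_adapters()` ships
  standard Illumina small-RNA sequences as documentation-grade examples;
  they must be replaced to match the actual library chemistry.
* **Qualities are carried, never used.** No quality trimming is applied:
  "quality reads" is taken to mean machine-passing reads.

# Matching and the exclusion database

Tag classification follows a strict precedence: a tag found as a
substring of any exon sequence is `EXCLUDED_MRNA` even if it also equals
a mature miRNA — degraded-mRNA removal comes first in the pipeline
order. miRNA matching is containment in either direction (tag within
mature, or mature within tag) at 0 mismatches by default, which treats
trimming slop symmetrically without an alignment model.

Exact containment queries run against a separator-joined reference text
using fixed-pattern search; the separator `#` cannot occur in a
nucleotide tag, so no query can straddle two sequences. Tests assert
that this lookup is extensionally equal to a naive per-sequence scan on
randomized instances (the oracle is re-derived independently in the test
code), so the representation is an implementation detail that cannot
change answers.

# The synthetic-data generator

Because the original sequencing libraries are not reproducible at desk
scale, validation uses a generator that emulates exactly the read
classes the filters target, over a toy reference:

* **Reference.** `n_mirnas` random mature sequences of 18–24 nt,
  rejection-sampled to be pairwise non-substring (so assignments are
  unambiguous); the first `n_multilocus` are planted at two genomic loci,
  the second on the minus strand (exercising reverse-complement
  extraction); exons are guaranteed free of mature sequences unless a
  decoy exon is requested for exclusion-precedence tests.
* **Reads.** Each read's class is drawn from one multinomial per sample:
  per-miRNA abundances, the four contaminant classes, and an
  unalignable remainder. miRNA reads are the exact mature sequence plus
  a uniform 6–18 nt prefix of the 3' adapter; contaminant classes are
  generated *mutually exclusively* (each read violates exactly the rule
  of its class), which makes the filter report exactly predictable from
  the truth table — the property the preprocessing tests assert. An
  adversarial mode draws flanks of 5 or 19 nt to exercise the rejection
  boundary.
* **Defaults** describe a plausible small-RNA library at desk scale: 30
  miRNAs (3 two-locus) absorbing 70% of reads with geometric (\(0.9^i\))
  abundance decay, 5% poly-A, 2% ambiguous, 3% 5'-adapter carry-over,
  10% degraded mRNA, 10% unalignable; 50,000 reads per sample. The read
  depth is enough that a planted 4-fold change on a ~1.5%-abundance
  miRNA is called essentially always, while keeping a 100-seed
  repetition affordable on one CPU.
* **Determinism.** All generation is a pure function of the
  configuration including its seed; identical configs give
  byte-identical FASTQ and truth files.

What the generator does *not* emulate: sequencing errors (an exact-match
world), isomiR end-variation beyond the containment slack, quality-value
structure, ligation bias, and miRNAs sharing sequence content. Passing
tests therefore demonstrate the correctness of the bookkeeping —
filtering fates, exclusion precedence, C/M/N accounting, fold algebra —
not robustness to base-calling noise; on real data the mismatch and
splitting knobs exist precisely because those idealizations break.

# Numerical and degenerate-input choices

* Collapsed tags are emitted in lexicographic order; ranking ties break
  lexicographically by name — all outputs are permutation-invariant and
  reruns are byte-identical.
* An empty FASTQ yields all-zero reports and RPKMs (no division by the
  zero library size) rather than an error, so a pipeline run over a
  degenerate sample completes with interpretable output.
* Coordinates are 0-based half-open internally; GFF3 and printed
  browser-style coordinates (1-based inclusive) are converted on load,
  BED is taken as-is. All sequences are compared in DNA space (U→T,
  uppercase).
* Names are taken verbatim: miR-31 and miR-31* are distinct entries; no
  arm merging or isomiR sub-annotation is attempted.

# Problem sizes used in the shipped checks

The packaged tests and the `analysis/` scripts run the generator at
1,500–100,000 reads per sample, 4–60 miRNAs and up to 1,000 tags against
100 reference sequences for the oracle-equivalence checks; the
differential-recovery experiment repeats the full
simulate–preprocess–classify–quantify–call path over 100 seeds at 50,000
reads per sample. These sizes were chosen as the smallest at which the
multinomial error bounds are meaningfully tight.

# Known limitations

* No genome-wide alignment: N is necessarily a proxy (see above), and
  tags matching neither exons nor matures are reported `UNALIGNED`
  rather than being located in the genome.
* No gapped or seeded alignment, no novel-miRNA discovery, no hairpin
  context, no replicate-aware statistics — calling is purely
  threshold-based, as in the comparison the package reproduces, and
  p-values are deliberately out of scope.
* The published rank columns cannot be verified absolutely (their
  detected-miRNA universe is not available); only internal ordering
  consistency is checked.
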
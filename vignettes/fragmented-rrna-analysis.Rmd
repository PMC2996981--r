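---
title: "Analysing fragmented mitochondrial rRNA genes with rRNAfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fragmented mitochondrial rRNA genes with rRNAfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rRNAfrag)
```

## Scope and model

`rRNAfrag` analyses *fragmented* (discontinuous) rRNA genes: genes whose
product is encoded by two or more genomic segments whose transcripts are
never covalently joined — unlike intron-containing genes, where splicing
restores a single molecule.  The motivating system is the mitochondrial
LSU rRNA of cupped oysters (*Crassostrea*), split into a 5' and a 3'
fragment on a circular genome of roughly 17–19 kb, with the two halves
separated by tRNA and protein-coding genes.  Five analyses interlock:

1. covariation statistics over RNA alignment columns, with greedy base-pair
   prediction;
2. template-based transfer of a secondary-structure model onto a new
   sequence, with per-domain presence calls;
3. gene-boundary inference from polyadenylated transcript (EST) evidence;
4. fragment-level sequence statistics (length, A+T content, pairwise
   identity matrices);
5. in-silico PCR with degenerate primers and the splicing-test decision
   rule.

A synthetic-data generator with known ground truth makes every stage
testable by parameter recovery.

## Coordinates and alphabets

All public coordinates are 1-based and inclusive (GenBank/GFF3
convention), because every published coordinate in this domain is
written that way.  On a circular molecule a feature with `start > end`
spans the origin; this avoids duplicating sequence and keeps arithmetic
exact (`intervalLength(95, 5, genomeLength = 100)` is 11).  Genomes are
stored as DNA (T), alignments and structures as RNA (U), with explicit
conversion at module boundaries.  Readers reject malformed input rather
than repairing it: a wrong coordinate or an illegal character is an
error naming the position.

The GFF3 reader is a direct 9-column parser rather than a GRanges-based
importer because origin-spanning features (`start > end`) have no
GRanges representation (negative width).  CT files use the Zuker
dialect (header `N title`, six columns); dot-bracket supports `()` plus
one pseudoknot layer `[]`.

## Covariation statistics

For columns $i,j$ and rows without a gap at either column (pairwise
deletion), mutual information is

$$\mathrm{MI}(i,j) = \sum_{x,y} f_{xy}\,\log_2\frac{f_{xy}}{f_x\,f_y},$$

bounded by $0 \le \mathrm{MI} \le 2$ bits on the 4-letter alphabet, and
the Pearson $\chi^2$ statistic is computed on the same observed joint
table with $df = (r-1)(c-1)$ over observed letter categories
(degenerate single-category tables yield $\chi^2 = 0$, $df = 0$).
Design choices worth stating:

- **Gap policy.** Pairwise deletion with the surviving row count
  reported as `n_eff` (default minimum 5 in `covariationMatrix()`), so
  loss of power is visible rather than silent.  A statistic that cannot
  be evaluated is `NA`, never 0.
- **No pseudocounts, no sequence weighting.** With few sequences MI is
  biased upward (of order $(|X|-1)(|Y|-1)/(2N\ln 2)$ bits); the
  prediction threshold absorbs this.  A weighting hook is left for the
  future but the baseline method predates weighting.
- **Greedy prediction.** `predictPairs()` sorts by MI (ties: higher
  $\chi^2$, then smaller $i$) and accepts a pair when both columns are
  unassigned, MI ≥ 0.15 bits (default), and — by default — the columns
  are each other's best partner over the whole table.  The threshold
  sits well above the small-sample bias at the standard simulation
  depth ($n = 100$: bias ≈ 0.065 bits) and well below the signal of a
  compensatory pair (≈ 1.2 bits, see below).  Tie-breaking is fixed so
  runs are reproducible.

The exact historical formulations behind early covariation software
were never published in full; the standard Shannon/Pearson forms are
used here and validated against brute-force evaluation of the defining
sums (to 1e-12 in the tests) rather than against any historical binary.

## Template-based structure mapping

`mapTemplate()` transfers a template pair set through a monotone
position map (from a 2-row alignment).  A pair survives only if both
positions map and the target letters form a canonical pair
({AU, UA, GC, CG, GU, UG} — standard comparative-model practice for
rRNA).  The report partitions template pairs exactly into retained and
dropped (with reasons `unmapped_i`, `unmapped_j`, `non_canonical`), and
each pair is attributed to the domain containing its 5' endpoint.

`domainPresence()` converts per-domain retention into qualitative
calls: absent below 0.1, present above 0.9, otherwise partial.  The
thresholds are configurable because published calls are qualitative;
the defaults make "absent" mean essentially no surviving pairs and
"present" mean essentially intact.  Domain and region maps (e.g.
peptide-exit-tunnel segments) are user-supplied interval tables on
template coordinates; numbering systems (such as *E. coli* numbering)
are treated as opaque labels that must match between inputs — no
default map is invented.  `fragmentationSiteCheck()` tests the strict
condition that the break region between the fragments lies after domain
II's end and before domain IV's start; a break exactly at a domain
boundary fails the strict test.

## Boundary inference from ESTs

`detectPolyA()` defines the tail as the longest terminal A-run allowing
at most one non-A base (defaults: `minRun = 8`, `maxMismatch = 1`,
both exposed because no operational definition is standard), trimmed so
the tail starts with an A.  `inferBoundaries()` then applies two rules:

- the 5' boundary is the extreme 5'-most transcript position, unless a
  known upstream gene ends 5' of it, in which case the boundary is the
  first nucleotide downstream of that gene;
- the 3' boundary is the modal polyadenylation site among tailed
  transcripts, required to reach a supporting fraction of at least 0.5
  (a literal majority); ties break toward the 3'-most site, which is
  conservative against truncation artifacts.

An important identifiability caveat: a templated A-run abutting the
true gene end cannot be distinguished from the tail by any detector, so
the polyadenylation site is operationally the last *non-A-run*
templated position.  The synthetic generator therefore forces the two
terminal gene bases to be non-A; on real genes whose 3' end is A-rich,
the inferred site will be systematically 5' of the annotated end.

For the *C. gigas* 5' fragment two starts have been reported (the first
nucleotide after the upstream tRNA, 5103, and the extreme transcript
position, 5117); both appear in the shipped coordinate table and the
package never silently merges them — `inferBoundaries()` reports which
evidence rule fired.

`fragmentSeparation()` returns both circular gaps and always satisfies
gap_a + gap_b + len(5') + len(3') = genome length.  With the published
*C. virginica* coordinates and the documented 17,244-nt genome length
the forward gap is 9958 nt.  (The corresponding published *C. gigas*
separation is not reproducible from its own published coordinates by
this arithmetic; the package reports what it computes and does not
adjust either input.)

## Sequence statistics

Percent identity uses Needleman–Wunsch global alignment (match +1,
mismatch −1, linear gap −2, via `Biostrings::pairwiseAlignment`) with
identity = identical columns / alignment length, rounded half-up.  The
denominator is configurable to "aligned columns only" because published
identity tables rarely state the convention; the two conventions differ
by a point or two on diverged fragments, which is why comparisons to
published tables carry a ±2-point tolerance.  A+T/G+C percentages are
rounded half-up and reconciled to sum to 100, with ambiguity codes
excluded from the denominator.  `similarityMatrix()` keeps the
asymmetric layout: upper triangle 5' fragments, lower triangle 3'.

## In-silico PCR and the splicing test

Degenerate primers are matched set-wise (a template base matches a code
iff it belongs to the code's set), scanned in linear time with a 4-bit
base encoding; circular templates are scanned across the origin.
Defaults: at most 2 mismatches overall and 0 in the 3'-terminal 3 bases
(polymerase-extension realism), maximum product 5000 bp (guards against
spurious giant circular products).  Annealing thermodynamics are not
modeled.

The splicing-test decision rule is a pure function of four evidence
bits (internal-5' product on cDNA, internal-3' product on cDNA,
spanning product on cDNA, spanning product on genomic DNA):

| spanning on cDNA | internal controls on cDNA | spanning on gDNA | verdict |
|---|---|---|---|
| yes | any | any | spliced_or_contiguous |
| no | both | no | not_spliced |
| no | any missing | any | inconclusive |
| no | both | yes | inconclusive |

All 16 combinations are tested against this table.  The
`spliceTestDemo()` fixture plants exact primer sites on a 3000-nt
synthetic genome (fragments at 501–900 and 2101–2500) and uses a
1000-bp product cap so that the 1200-nt genomic distance between
fragments is unamplifiable, reproducing the geometry — not the scale —
of the real experiment, where ~10 kb separates the fragments and the
spanning product is ~750–780 bp on a contiguous template.

## The synthetic-data generator

Defaults emulate the *C. virginica* architecture: a 17,244-nt circular
genome, fragments at 8250–8997 and 1712–2430, tRNA/CDS spacer genes
packed between the halves, a tRNA ending immediately before the 5'
fragment and a CDS immediately before the 3' fragment (their
polyadenylated transcripts bound the rRNA fragments, as in real EST
data).  ESTs (default 200 per gene) are 5'-truncated with per-base
geometric probability 0.01, substituted at 0.005 per base, and given
non-templated Poisson(30) poly(A) tails appended after truncation and
error — matching cDNA reality.  The genome is AT-rich (65%), typical of
molluscan mitochondria.  Alignments with covariation use star-phylogeny
sampling: each sequence independently resamples each template pair from
the six canonical pair types with probability `pairSubRate` and
substitutes unpaired positions at `bgSubRate`.  A star phylogeny is the
simplest model that produces covariation; tree-structured evolution,
indels, and quality scores are deliberately out of scope, so passing
recovery tests demonstrate correctness of the statistics and decision
rules, not robustness to phylogenetic correlation or alignment error in
real data.

All emissions are reproducible from (config, seed); each generator
seeds a single RNG stream explicitly.

## Problem sizes and determinism

The standard validation conditions are: covariation recovery on a 60-nt
structure with 15 pairs, 100 sequences, pair substitution 0.8,
background 0.1 (prediction PPV and recall are 1.0 at the shipped
seeds); boundary recovery on the full-size default genome with 200 ESTs
per run, 20 seeded runs (20/20 exact at default noise; the tolerated
failure mode is a modal-site tie).  These sizes keep the whole suite
fast while leaving the statistics well inside their asymptotic regimes.

## Known limitations

- GenBank sequences are not redistributed; accession-level statistics
  (fragment base composition, the 233-bp diagnostic product, identity
  matrices between real fragments) require user-supplied FASTA files
  via `options(rRNAfrag.genbankDir = ...)`.
- No de-novo folding, covariance models, APC correction, or
  significance calibration of MI; no spliced alignment of ESTs; no
  melting-temperature prediction.
- `alignEstsToGene()` is an exact/affine pairwise matcher intended for
  the synthetic data, not a general EST aligner.
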
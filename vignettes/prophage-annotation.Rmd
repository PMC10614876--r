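---
title: "Annotating prophage integrations by homology-match defragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating prophage integrations by homology-match defragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Temperate bacteriophages integrate into bacterial chromosomes and persist
there as prophages. Finding the integrated copies of a known phage across a
collection of bacterial genomes is, on its face, a homology search: align
each query phage against each genome and keep the significant hits. In
practice the integrated copies are often heavily diverged from the query,
and they frequently carry large insertions (transposons, other mobile
elements) or deletions relative to it. Alignment tools respond to such
interruptions by reporting one biological integration as several separate
alignment fragments lying near each other on the chromosome. Any analysis
that counts, measures, or classifies integrations directly from raw hits
will therefore overcount events and undercall full-length prophages.

`prophagr` implements the post-processing that fixes this: it filters raw
homology matches, chains fragmented matches back into single *integration*
calls under explicit joinability criteria, labels each integration full
length or partial by its coverage of the query phage, and exports the
results in tabular and JSON forms, including per-position occurrence
profiles along each query. It consumes hits from `nhmmer` tabular output,
BLAST 12-column tabular output, or a built-in naive detector that makes
the whole pipeline runnable without any external search tool.

## The joining model

Let a *match* be one homology hit of a query phage (length $n$) against a
target genome, with 1-based inclusive coordinates on the forward strand of
both sequences and a strand flag. Consider two matches with the first
preceding the second along the genome. They are *joinable* — fragments of
one integration — exactly when all four criteria hold:

* **A (same event):** both matches name the same query phage, the same
  target sequence, and the same strand. A single integration event cannot
  scatter colinear fragments across strands or queries.
* **B (colinearity):** the matches occur in the same order on the query as
  on the genome; on the minus strand the query order is mirrored.
* **Ca (bounded genome gap):** with $i$ the first match's end and $j$ the
  second match's start on the genome, $|i - j| \le k \cdot n$. The gap
  fraction $k$ defaults to $0.25$: an inserted element longer than a
  quarter of the query phage is treated as separating two events.
* **Cb (bounded query overlap):** with $s$ and $t$ the adjacent query-side
  boundary coordinates in genome order, fragments overlapping on the query
  by more than $\theta$ nucleotides (default $50$) are not joined —
  extensive overlap means two copies of the same phage region, not one
  fragmented copy. Gaps on the query are *never* penalized: they are the
  signature of deletions in the integrated copy, which fragment joining
  exists to tolerate. The overlap-only reading of Cb is a deliberate
  design choice; a literal two-sided bound $|t - s| \le \theta$ would
  contradict the deletion-tolerance requirement.

`assign_integrations()` applies these criteria with a greedy left-to-right
scan within each (target, query, strand) group, sorted by genome position
(ties broken by match end, then query start, so the scan is
deterministic). Each match either extends the chain of the immediately
preceding group member or starts a new chain; each chain becomes one
integration with a deterministic id `<target>_<ordinal>` numbered along
the genome. Grouping before scanning means a match to phage B sitting
between two fragments of phage A does not break A's chain — interleaving
is common at real tandem and nested integration sites, and criterion A
would forbid the cross-query link anyway. On random instances this greedy
scan provably computes the same partition as linking all consecutive
joinable pairs and taking connected components; the test suite checks
this equivalence against an independent graph-based oracle.

Upstream of joining, `filter_matches()` discards matches with E-value
above `evalue_max` (default $10^{-5}$, inclusive: "fails to meet the
threshold" is read as strictly exceeding it) and, optionally, matches
shorter than `min_match_length` on the genome (default 0; a survey
focused on phage-scale elements might use 1,000 nt). Filtering applies
per match, before joining.

Downstream, `call_full_length()` labels an integration full length when
the union of its fragments' query intervals covers at least
`full_length_fraction` of the query (default $0.70$, inclusive at the
boundary). Using the union — rather than any single fragment — is what
makes a rejoined fragmented copy count as one full-length prophage.

## Parameters

| parameter | symbol | default | units | role |
|---|---|---|---|---|
| `evalue_max` | — | 1e-5 | — | match significance cutoff (inclusive) |
| `gap_fraction_k` | $k$ | 0.25 | fraction of $n$ | genome-gap bound for joining |
| `max_query_overlap_theta` | $\theta$ | 50 | nt | query-overlap cap for joining |
| `full_length_fraction` | — | 0.70 | fraction of $n$ | full-length coverage threshold |
| `min_match_length` | — | 0 | nt | per-match genome-length floor |

All five live in `pipeline_config()`; the command-line layer exposes them
as flags, with a YAML config file in between (flags > file > defaults).

## Occurrence profiles

`build_profiles()` summarizes where, along each query phage, the detected
integrations fall: position $p$ of a query receives one count for every
integration whose query coverage includes $p$. Each integration counts
once per position (the union over its fragments), so overlap between
fragments of one rejoined integration is not double-counted. The profile
satisfies a conservation identity — the counts sum to the total query
coverage of the contributing integrations — which is asserted on every
build and re-checked in the tests. Profiles, integration records, and
fragment records are serialized by `export_summary_json()` under a
versioned schema (`inst/schema/summary-schema.json`), and integration
spans are exported as BED6 (0-based half-open, converted from the
internal 1-based inclusive convention) by `export_bed()`.

## The simulator and what it does (not) emulate

`simulate_dataset()` builds test genomes with known answers: i.i.d.
background sequence at a configurable GC fraction, random query phages,
and planted integrations in three modes — *full* copies, *truncated*
contiguous slices (slice fraction drawn from `truncation_range`, default
0.2–0.9, straddling the 0.70 boundary so both full-length labels occur),
and *fragmented* copies split around an inserted background spacer whose
length is `spacer_fraction` of the query (default 0.10, inside the
default $k = 0.25$, so such plantings should be rejoined; setting it
above $k$ manufactures negative controls). Plantings insert rather than
overwrite, may go on either strand (reverse complement), and may carry
point substitutions at `substitution_rate`. Ground truth — piece
coordinates on the final genome and on the query, strand, and the
expected full-length label under the 70% rule — is emitted alongside.

Defaults: 100 kb genomes, two 10 kb queries (the scale of filamentous
Inovirus-like prophages), three plantings per genome, GC 0.5,
substitution rate 0. These sizes keep a full
simulate–detect–join–evaluate cycle under a second while leaving room
for several well-separated phage-scale insertions.

Two design choices keep the ground truth exact and well-defined:

* **Substitution-only mutation.** With no indels inside a planted piece,
  every truth coordinate remains exact and recovery can be scored without
  alignment. Indel tolerance is exercised instead by the fragmented mode,
  which is precisely the scenario the joining step exists for.
* **Separated insertion points.** Insertion points are kept at least
  $0.3 \times$ the query length apart. Two independent plantings of the
  same query closer than $k \cdot n$ on the genome are *legitimately*
  joinable under the criteria — the method cannot, even in principle,
  distinguish that arrangement from one fragmented integration — so
  without separation the "one planting, one integration" ground truth
  would be ill-defined rather than merely hard.

What the simulator does **not** emulate: real genomic base composition
and repeats, phage gene architecture, recombination between copies,
att-site structure, and sequencing artifacts. Passing the planted-truth
suites therefore demonstrates the correctness of the filtering, joining,
and calling logic under controlled conditions — not search sensitivity on
real, diverged prophages, which is the province of the profile-HMM search
tools whose output the package consumes.

## The built-in detector and numerical choices

`naive_detect()` is an exact-seed, ungapped-extension detector: all
shared `seed_kmer`-mers (default 15) between query (both strands) and
genome are found via a k-mer index, seeds on a common diagonal are merged
into exact runs, and each run is extended in both directions until the
running score drops `xdrop` (default 20) below its maximum, then trimmed
to the maximum-scoring extent. Overlapping extents on one diagonal are
merged. `N` participates in no seed and matches nothing.

Numerical choices worth knowing:

* **Extension weights.** Extension is trimmed under $+1$ match / $-3$
  mismatch, the usual weights for ungapped nucleotide seed extension. A
  $-1$ mismatch penalty makes the extension a nearly driftless random
  walk in background sequence, whose maximum-scoring extent creeps past
  a copy boundary by 15+ nt a few times per hundred boundaries; the $-3$
  penalty keeps reported boundaries within one seed length of the true
  edge essentially always. The *reported* score stays the plain
  match-minus-mismatch count over the final extent.
* **Reporting floor.** Naive hits carry `evalue = 0` (the detector has no
  statistical calibration, and the E-value filter passes them through),
  so a `min_score` floor (default `2 * seed_kmer`) plays the role a
  significance threshold plays for calibrated tools: it suppresses the
  ~seed-length chance hits that a lone shared 15-mer produces.
* **Inclusive boundaries everywhere.** `evalue <= evalue_max`, genome gap
  `<= k * n`, overlap `<= theta`, coverage `>= fraction * n`: every
  printed threshold is attained exactly at its boundary, and the
  acceptance sweeps verify each one.
* **Coordinates.** All internal and on-disk coordinates are 1-based
  inclusive with `start <= end` plus a strand flag (the convention of the
  HMMER tool family); BED export converts to 0-based half-open. Query
  coordinates always refer to the query's forward strand.

## Problem sizes used by the test suite

The shipped suites run the joining oracle on 1,000 random instances of up
to 10 matches; planted-truth recovery on 50 simulated genomes at the
default configuration (150 plantings) plus 10 gap-violating negative
controls; and 5%-divergence robustness on 8 replicates. These sizes give
the properties enough trials to be meaningful while keeping a full test
run in the low minutes on one core.

## Known limitations

* The naive detector requires exact 15-mer seeds; beyond roughly 15–20%
  divergence its sensitivity collapses. It is test scaffolding and a
  fallback, not a search method.
* No combined significance is computed for a joined integration; per
  fragment E-values are reported as-is.
* The greedy chain extension consults only the immediately preceding
  group member; pathological overlapping-hit configurations that a full
  dynamic-programming chainer would resolve differently are possible,
  though the connected-components equivalence bounds how far the greedy
  result can stray on realistic inputs.
* Attachment-site (att) detection and phage gene-level annotation are out
  of scope; the package annotates integration extents and identity only.
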
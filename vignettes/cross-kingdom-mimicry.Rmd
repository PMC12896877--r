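---
title: "Screening plant miRNAs for cross-kingdom mimicry of host miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plant miRNAs for cross-kingdom mimicry of host miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xkmir)
```

## The problem

Edible-plant nanovesicles — for example vesicles recovered from orange juice —
carry plant mature miRNAs into mammalian tissue. A plant miRNA whose
sequence, and above all whose *seed* (nucleotides 2–7 from the 5′ end),
closely matches a host miRNA could load into the host silencing machinery and
regulate the host miRNA's targets: cross-kingdom mimicry. `xkmir` implements
the desk half of that question as a reproducible pipeline:

1. **align** every plant ("query") miRNA against a host miRNA catalogue with
   a global aligner and keep each query's best hit;
2. **filter** hits whose seed did not align properly;
3. **predict targets** of both members of each surviving pair on host 3′UTRs
   by canonical seed-site scanning, keeping the top-*k* genes per miRNA;
4. **test overlap** of the two target sets with a one-sided Fisher's exact
   test over the UTR gene universe;
5. run **over-representation analysis** (ORA) of each target set against a
   flat term annotation.

A seeded synthetic-data generator plants mimic pairs, target sites, and one
enriched term with known truth, so the sensitivity and the false-positive
behaviour of every stage can be measured without any external download.

## The mimicry aligner

Mature miRNAs are 19–24 nt single strands written 5′→3′; we align query
against host globally (Needleman–Wunsch), never against the reverse
complement, matching the convention of mature-miRNA catalogues. The
substitution scheme is deliberately *mismatch-averse*: relative to unit
scoring, matches reward more and mismatches and gaps cost more, so only
near-identical sequences — in particular, sequences with an intact seed —
reach high scores. Exact values are tunable; the defaults are

| parameter | default | unit |
|---|---|---|
| match | +2 | score/column |
| mismatch | −3 | score/column |
| gap open | −4 | score/column |
| gap extend | −4 (linear) | score/column |

A gap of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$; with the
defaults the model is linear. An affine model is available by making
`gap_extend` milder than `gap_open`; opening must be at least as costly as
extending, which keeps the two-state Gotoh recursion exact. At 30 nt or less,
affine gaps change little, but they are cheap to support.

Dynamic-programming ties are broken deterministically (diagonal > up > left;
extend an existing gap rather than re-open), so the screen is a pure function
of its inputs — rerunning any catalogue gives byte-identical tables. The DP
is verified in the test suite against an independent oracle that enumerates
*every* global alignment of short random pairs.

**Seed filter.** A best hit survives only if, within the alignment columns
spanned by query positions 2–7, (i) neither row has a gap and (ii) at least
`min_matches` columns are identical (default 6 — the strictest reading of a
6mer seed). G:U wobble counts as a mismatch: wobble pairs do occur in real
seed pairing, and the threshold is exposed (`min_matches = 5` approximates a
laxer manual review), but the default stays strict because the screen's job
is to shortlist, not to be exhaustive. Ties between equally scoring hosts go
to the higher seed-match count, then the lexicographically smaller host id.

## Target prediction

For a miRNA with seed $s$ (positions 2–7), a target site on a UTR (mRNA
sense) is an occurrence of the reverse complement of $s$. Because pairing is
antiparallel, the UTR base pairing miRNA position 8 lies immediately 5′ of
that core, and the base opposite miRNA position 1 immediately 3′ of it. The
canonical classes follow: `7mer-m8` (match at position 8), `7mer-A1` (an A
on the UTR opposite position 1 — the t1A rule, an A regardless of the miRNA
base), `8mer` (both), `6mer` (neither).

Sites are scored with a transparent stand-in for thermodynamic models:
class weight (8mer = 4, 7mer-m8 = 3, 7mer-A1 = 2, 6mer = 1) plus 0.5 × the
A/U fraction of the flanking ±30 nt (site excluded; zero when no flank
exists). AU-rich context correlates with site accessibility; the 0.5 weight
keeps the bonus strictly inside the gap between class weights, so classes
never reorder. The scorer is a plug-in argument of `scan_sites()` /
`predict_targets()`, so a thermodynamic scorer can be substituted without
touching anything downstream: the overlap and enrichment statistics depend
only on the ranked top-$k$ sets, not on absolute scores.

Per UTR only the best site is kept (ties to the 5′-most), genes are ranked
by score (ties by gene id), and the top $k=100$ genes define the miRNA's
putative target set. $k$ is the conventional shortlist size for this kind of
screen and is configurable.

## Overlap and enrichment statistics

For each seed-passing pair we form the 2×2 table of the two target sets over
the universe — all genes with a UTR record, the same universe for both
members, logged in every output row — and compute the one-sided (enrichment)
Fisher exact p-value, which is the hypergeometric upper tail
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$. Shared targeting is
an inherently one-directional question; a two-sided variant is available via
a flag. Degenerate margins (an empty target set) carry no information and
give $p = 1$ by convention. BH adjustment runs across all pairs tested in a
run.

ORA uses the same tail: for every term with ≥ 1 hit and at least
`min_term_size` (default 5) background genes, $p = P(X \ge k)$ for $k$ hits
of a size-$n$ set against a size-$K$ term in a size-$N$ background, BH
adjusted per gene set. The annotation is a flat term→gene map: GeneRatio is
$k/n$ and BgRatio $K/N$, and $n$ counts only set genes present in the
background, so set sizes vary slightly between miRNAs even at fixed $k$.
No ontology graph is modeled; any term propagation must happen upstream.
Published report tables of this kind mix per-branch backgrounds
(e.g. 21,081 vs 21,872 vs 20,616) across rows; `xkmir` uses a single
background per run and records it in every row. The tail is computed by
`stats::phyper`, which is accurate in log space down to ~1e-300; the test
suite checks it against direct summation and against exhaustive enumeration
of small universes.

## The synthetic-data generator

`sim_config()` describes a synthetic study; the defaults are fixed study
conditions, not tuning knobs:

* catalogues of 19–24 nt miRNAs, i.i.d. uniform bases; one planted mimic per
  study among 50 hosts, sharing the seed exactly and carrying 3 substitutions
  outside it — a realistic "similar but not identical" homolog;
* UTRs of 200–800 nt (300 per study) with optional planted sites whose
  flanks are set to satisfy, or deliberately violate, a requested class;
* a flat annotation of 50 terms of 5–60 genes, with one truth term of 40
  genes, 75% of which are forced into a designated 100-gene set (an
  unambiguous enrichment signal at background 5000).

An `au_bias` knob shifts base composition, because real citrus UTRs are not
uniform and the site scorer has an AU term; tests use it to decouple class
weights from the context bonus. Generation uses only R's integer-seeded RNG
and is byte-deterministic given a config.

What the generator does *not* emulate: expression levels and read counts
(inputs are already catalogues, as after miRDeep2-style quantification),
miRNA families and isomiRs, UTR composition structure beyond a global AU
bias, conserved site clustering, and ontology structure in the annotation.
Passing tests therefore demonstrate correctness of the algorithms and
calibration of the statistics under these controlled conditions — not that
any particular biological pair is a true mimic.

## Numerical and design choices

* **Alignment determinism** — tie preferences as above; identical inputs give
  identical candidate tables on any platform.
* **Seed span with gaps** — if the best alignment places a gap inside the
  query's 2–7 span, the candidate fails the filter regardless of identities;
  `min_matches` applies to gapless spans.
* **Degenerate inputs** — empty FASTA files, empty candidate lists, and gene
  sets with no annotated gene short-circuit to empty results (with warnings)
  rather than errors, except where silence would corrupt statistics: set
  members outside the declared universe are always an error, and IUPAC
  ambiguity codes are rejected at parse time because a single N would corrupt
  seed matching silently.
* **Problem sizes** — the shipped tests and the acceptance script run the
  full pipeline at 5 queries × 40 hosts × 200 UTRs, the aligner oracle on
  500 short pairs, recovery/null screens at 200 replicates and the
  enrichment null at 500 replicates; these sizes give stable rates (binomial
  s.e. ≤ 2.3 points) while keeping a complete run in well under a minute.
* **Reporting** — every stage writes plain TSV with a `# params:` provenance
  comment; `summary.json` echoes the parameters and the stage counts.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, n_query = 5, n_host = 40, n_mimic_pairs = 3,
                  n_utrs = 200, utr_len_range = c(300L, 600L))
dir <- tempfile()
gen_study(cfg, dir)
run <- run_pipeline(run_config(
  query_fa = file.path(dir, "query.fa"),
  host_fa = file.path(dir, "host.fa"),
  utr_fa = file.path(dir, "utrs.fa"),
  annotation_tsv = file.path(dir, "annotation.tsv"),
  out_dir = file.path(dir, "out")))
run
read_stage_tsv(file.path(dir, "out", "overlap.tsv"))
```

The three planted pairs pass the seed filter, dominate the overlap table
with BH-adjusted p-values far below 0.05, and the planted term tops the
per-set ORA of its designated gene set.

## Known limitations

* The site scorer is intentionally simple; absolute scores are not
  comparable to thermodynamic predictors, only ranks within a run are
  meaningful.
* The overlap universe is defined by the UTR FASTA; results are sensitive to
  that choice, which is why it is logged per row.
* ORA treats terms as independent flat sets; correlated (nested) terms
  inflate the number of tested hypotheses exactly as in standard ORA
  practice.
* The screen tests sequence mimicry only; it says nothing about vesicle
  loading, delivery, or in-cell activity.
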
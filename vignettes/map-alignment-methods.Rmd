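---
title: "Aligning error-prone genomic maps to sequences: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning error-prone genomic maps to sequences: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmapalign)
```

## The problem

Genome-mapping platforms (OpGen Argus, BioNano Irys and similar) read single
DNA molecules of 150 kbp to 2 Mbp as an *ordered list of fragment sizes*
between occurrences of a short recognition pattern - no base-level sequence,
just continuous-valued lengths. Anchoring those error-prone maps onto an
assembly's in-silico digest is the step that makes them useful for
scaffolding, assembly validation and structural-variant analysis. The
difficulty is the error process: roughly one in four true cuts is missed,
spurious cuts appear at about one per 100 kbp, fragments below the detection
limit (~2 kbp) vanish, and every size is measured with a few percent of
noise. `rmapalign` implements a seed-and-extend aligner for this data type
with a statistical read-out that does not need the error rates as input.

Two alignment modes are provided. A **glocal** alignment places an entire
experimental map inside a reference map (`align_maps()`); an **overlap**
alignment lets the maps overhang each other's ends, which is what scaffold
extension needs (`overlap_align_maps()`).

## Data model and feasibility

An experimental map is `o_1..o_m` (bp); a reference map `r_1..r_n` carries
per-fragment standard deviations `sigma_j`. A *match* pairs a block of
consecutive experimental fragments with a block of consecutive reference
fragments; it is *feasible* when

```
| sum(o_i) - sum(r_j) |  <=  C_sigma * sqrt(sum(sigma_j^2))
```

with `C_sigma = 3`, appropriate if sizing errors are roughly normal. End
matches of a map may be truncated (the molecule was cut mid-fragment), so at
map ends only a one-sided version of the bound applies: an upper bound when
the experimental end fragment may be short, a lower bound at reference ends.
We read both relaxations as magnitude caps on the truncated side; written
out with both signs explicit, the lower-bound case is
`sum(o) - sum(r) >= -C_sigma * sqrt(sum(sigma^2))`.

No published table maps reference fragment size to `sigma_j`; the
technology-dependent choice is left to a `sigma_model(rho, sigma_min)`
function, by default `sigma_j = max(300 bp, 0.05 * r_j)`. A 5 % relative
error with an absolute floor reproduces the qualitative size dependence of
observed sizing errors (small fragments are relatively much noisier) while
staying fully configurable; every feasibility test in the package goes
through whatever model the reference table carries.

## Composite seeds over continuous values

A 2-mer of consecutive fragment sizes is a weak anchor when 22-39 % of cuts
are missing, so the index stores, for every reference position `j`, the
tuples `(r_j, r_{j+1})`, `(r_j + r_{j+1}, r_{j+2})` and
`(r_j, r_{j+1} + r_{j+2})` - the last two pre-absorb one missing cut. At
query time both `(o_i, o_{i+1})` and `(o_i + o_{i+1}, o_{i+2})` are looked
up, covering one false cut on the experimental side. Seeds use a stricter
per-element bound `C_sigma_seed = 2`, since anchors should be high-quality
fragments.

Entries are sorted by their first element. Because `sigma` varies per entry,
a plain multiplicative search interval is not safe for arbitrary sigma
models; the index instead precomputes two monotone envelopes - the running
maximum of `key + C * sd` and the suffix minimum of `key - C * sd` - and
brackets the scan between the first index whose envelope reaches the query
and the last index whose envelope has not passed it. Every entry outside
that bracket provably fails its own test, so lookup is a binary search plus
a verified linear scan with no loss of completeness. Seeds are deduplicated
by `(reference, strand, reference position, query position)` before
extension; the reverse strand is searched by reversing the query rather
than doubling the index.

## Extension by banded dynamic programming

A seed is extended on both sides to an alignment that minimizes, in
lexicographic order, the total number of *cut errors* (missing cuts + false
cuts + missing fragments) and then the sizing chi-square
`sum_k (sum(o) - sum(r))^2 / sum(sigma^2)` over matches. The combined score
`C_ce * #cut_errors + chi2` with `C_ce = C_sigma^2 * m + 1` realizes exactly
that order, because each of the at most `m` feasible matches contributes at
most `C_sigma^2` to the chi-square; the test suite verifies the equivalence
against a two-stage enumeration oracle.

The dynamic programming over (query index, reference index) states is
banded by the error limits a single match may carry - at most 5 consecutive
false cuts and 8 consecutive missing cuts - and an extension is abandoned
when no feasible match has appeared after `f = 5` query fragments on a
side. A reference fragment of at most 2 kbp inside a match may be declared
*missing* (excluded from the sums) only when that halves the match's
chi-square relative to the best alternative that keeps it, or when keeping
it admits no feasible match at all; at most 3 consecutive fragments may be
skipped, and skipping leaves the neighbours' sizes untouched. Counting a
missing fragment as one cut error makes the skip cost-neutral in the error
total, which is why the chi-square halving gate is needed to stop
promiscuous skipping. Within these rules the engine (implemented in C++,
as the inner loop runs thousands of times per map) is exact: on random
instances with `m <= 6`, `n <= 12` it reproduces an exhaustive enumeration
of all banded partitions to 1e-9.

Two decisions the description of the method leaves open are fixed as
follows. The halving rule's "nearby matches" is interpreted as the match
being formed (the directly affected one). Truncated one-sided end matches
count towards `#matches` but contribute no chi-square term by default
(`include_truncated_chi2 = FALSE`), since a truncated fragment's sizing
deviation is not meaningful; remaining ties are broken towards fewer
matches, then the leftmost reference start, for determinism.

## Statistical evaluation without error-rate priors

All feasible extensions of all seeds of one map - after structural
deduplication - form the candidate population `Pi`. Under the assumption
that at most one candidate is the true placement, the rest approximate a
draw from a conservative null. Each candidate is summarized by three
features: number of matches, total cut errors, and the Wilson-Hilferty
cube-root transform of its chi-square,

```
WHT(chi2, n) = ((chi2/n)^(1/3) - (1 - 2/(9n))) / sqrt(2/(9n)),
```

which is approximately standard normal and comparable across alignment
structures. Features are Z-standardized over `Pi` (population SD; a
zero-spread feature standardizes to 0 and simply drops out), summed with
signs (-1 for matches, +1 for the error features), re-standardized, and
converted to `p = Phi(theta)`. The candidate with the smallest p-value is
reported.

Significance of the best candidate is controlled by FDR across maps:
Benjamini-Hochberg over best-candidate p-values within strata of comparable
maps (fragment-count bins of width 2, merged until a stratum holds at least
50 maps - per-count strata are too small for stable FDR at desk scale), at
`q <= 0.01`. Uniqueness requires the next-best candidate at a *different*
locus to have a p-value at least 5 times larger (30 is the recommended
stringent setting for noisy real data). Populations with fewer than 60
candidates are flagged `low_population` (the normal approximation of the
feature means is weakest there); a single-candidate population cannot be
standardized and is reported `non_significant`.

## Overlap mode

`overlap_align_maps()` slides a window of `window_l = 12` fragments (step
1) along the map, solves each window as a glocal sub-problem, and pools all
window solutions for the q-value analysis. Ranked by p-value, solutions are
taken best-first; iteration stops at the first non-significant or
non-unique solution, and a solution is skipped when it duplicates an
already-reported overlap, conflicts with a better-ranked pick, or is not
clearly better than a worse-ranked solution it conflicts with (ratio below
the uniqueness threshold). Two window solutions *conflict* when their
windows overlap or when they place the map on the same reference at a
different location or strand; "same location" is operationalized as
implied whole-map positions within `conflict_tol_bp = 50 kbp`, generous
against sizing drift over a window but far below any distinct locus.
Survivors are extended with the same DP in overlap mode, where each side
may terminate at a reference end (one-sided lower bound) instead of the
query end, preferring longer alignments; reports include how many
experimental fragments protrude past each scaffold end, the raw material
for scaffold extension. The window length trades sensitivity (short
windows fit inside more true overlaps) against identifiability (short
windows are noise-like); the suite checks that 12 performs at least as
well as 6 and 20 on a simulated fragmented assembly.

## The simulator

`simulate_maps()` generates benchmark maps with truth logs, emulating an
optical-mapping run on a reference:

1. a target fragment count is drawn as `4 + NegBin(size 6, mu 13)` (mean
   17 fragments, the published average; the full empirical map-length
   distribution is not public, so a modestly overdispersed count
   distribution stands in) and converted to a bp extent using the
   experimental average fragment size, i.e. the reference AFS divided by
   the digestion rate;
2. a start is sampled uniformly, possibly truncating end fragments;
3. each interior true cut is kept with probability `d` (Binomial missing
   cuts);
4. false cuts arrive as a Poisson process with rate `f100` per 100 kbp,
   re-drawn up to 100 times if a placement would create a fragment under
   1.2 kbp, then skipped (the rejection rule needs a termination
   guarantee);
5. small fragments vanish with size-dependent probabilities; the removed
   fragment's flanking cuts collapse to one and its neighbours keep their
   own sizes, which is exactly the situation the aligner's
   missing-fragment gap models;
6. sizes are perturbed by Gaussian relative error truncated at 3 SD, with
   SD 15 % below 2 kbp, 8 % to 10 kbp, 5 % above (a parametric stand-in
   for unpublished empirical deviation tables, configurable per run);
7. maps under 150 kbp or 10 fragments are discarded and redrawn,
   mimicking instrument pre-processing, and each map is reported on a
   random strand.

Two presets reproduce the benchmark conditions: scenario A (easier,
`d = 0.78`, `f100 = 0.97`, missing-fragment probabilities 0.5 under
1.2 kbp / 0.75 under 600 bp / 1 under 350 bp) and scenario B (harder,
`d = 0.61`, `f100 = 1.38`, 0.5 under 2 kbp / 0.75 under 800 bp / 1 under
350 bp). `synth_reference()` supplies a reference stand-in with
exponential fragment sizes (floored at 100 bp), matching a genome digest's
AFS but not its long-range repeat structure - so simulation results show
error-model robustness, not repeat resolution. `simulate_assembly()`
fragments a reference into scaffold-sized pieces (log-normal sizes
calibrated so the length-weighted median matches a target N50) and drops
pieces with fewer than 4 non-end fragments, which cannot be confidently
aligned.

## Numerical and scale choices

All randomness flows through explicit seeds; `set.seed` derivations keep
integer state. Population (not sample) SDs are used throughout the Z
machinery, matching the convention that two candidates `{0, 2}` score
`{-1, +1}`. Degenerate situations are defined rather than special-cased
downstream: zero-spread features give Z = 0, an empty stratum falls back
to the global population, reports carry explicit `status` strings for
rejected or unalignable maps.

The test suite runs its heavier checks at sizes chosen to exercise the
statistics without excessive runtime: DP-oracle equivalence on 500 random
small instances; seed completeness on 1,000 scenario-A maps against a
10,000-fragment reference; false-discovery control on 2,000 maps (half
drawn from a decoy reference) against a 2,000-fragment reference; the
acceptance script's seed-sensitivity anchors use a 50,000-fragment
human-like reference (AFS 10.8 kbp) and 1,000 maps per scenario. Full
glocal alignment against a reference that large is far heavier - the
candidate population of a single map grows with reference density - which
is why the population-level checks use the smaller references.

## Known limitations

- Only seed order `c = 2` is implemented; higher orders and multi-error
  seeds are out of scope.
- The exponential synthetic reference has no segmental duplications or
  repeat families; uniqueness behaviour on real genomes will be harsher.
- The q-value method is Benjamini-Hochberg; a Storey-type pi0 estimate
  could be slightly less conservative on strongly enriched strata.
- Chimeric/spurious molecules are not simulated (the generator models a
  single contiguous source interval per map).
- In-silico maps are taken at face value: sequencing or assembly errors in
  the reference are not modelled.
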
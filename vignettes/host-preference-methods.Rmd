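---
title: "Quantifying host preference in epiphytic communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host preference in epiphytic communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostpref)
```

## The question and the data model

Epiphytic lichens grow on bark but feed from the atmosphere, so host
identity is often assumed not to matter to them. The counter-evidence is
distributional: across a region, a substantial share of epiphyte species
may be recorded on exactly one host species. `hostpref` quantifies that
share from the simplest data that can support it: long-format presence
records, one row per (epiphyte taxon, host taxon, grid cell, geographic
area). There is deliberately no abundance field — a record asserts
presence, and repeated (epiphyte, host, cell) rows are collapsed on input.
Grid-cell codes are opaque sampling-unit labels (no geometry is parsed) and
each cell belongs to exactly one area; both constraints are validated at
read time. Taxon labels are matched exactly after whitespace
normalization: no synonymy resolution is attempted, and a label determined
only to genus is treated as a taxon like any other. That is the honest
choice for compiled occurrence data, and its consequence — lumped labels
deflate, split labels inflate apparent exclusivity — is the user's to
manage upstream.

## Exclusivity at two scales

The host range of an epiphyte is its number of distinct hosts within an
evaluation scope; the exclusivity count is the number of epiphytes with
host range 1. The scope matters, and the package fixes it as follows:

- **Regional (pooled)**: host ranges over the full dataset
  (`host_table()`, the pooled row of `area_table()`).
- **Local (per area)**: host ranges recomputed from that area's records
  alone (`area_table()`). A species using one host inside an area counts as
  locally exclusive even if it uses others elsewhere. This is the scope
  under which local percentages can exceed the regional one — regional
  pooling can only grow a species' host range.

Percentages are rounded half-away-from-zero to one decimal
(`round_half_away()`); base R's round-half-to-even would differ on exact
halves, and table output fixes one decimal so CSVs are stable. Ranking
ties (hosts by cell count, epiphytes by host range) break alphabetically,
which keeps outputs deterministic across platforms. A species recorded in
a single cell is still eligible for exclusivity — no minimum-occurrence
filter is applied, and users should remember that a species seen once is
exclusive by construction.

Degenerate inputs are defined, not errors: restricting a cube to zero
cells yields an empty cube with exclusivity count 0 and an undefined
percentage (`NA`); unknown cell ids in a restriction are dropped with a
warning so curve code stays simple.

## Accumulation curves

The exclusivity count at full sampling says little about whether the
pattern is a small-sample artefact. The accumulation curve answers that:
incorporate cells one at a time in random order, recompute the exclusivity
count after each, and average over many orders (default `n_perm = 99`,
configurable), plotting the per-step mean with min/max envelopes. Early
steps overshoot — with few cells, a generalist's other hosts have simply
not been seen — and the curve settles toward the full-data count as
sampling saturates.

Implementation notes:

- **Engine.** Recomputing from scratch at every step is O(cells ×
  records). Instead, for a given order each (epiphyte, host) pair
  *activates* at the first step that includes one of its cells; an
  epiphyte is exclusive from its first pair activation up to (not
  including) its second. One pass over pairs plus a difference array gives
  the whole trajectory. The naive per-step recomputation is retained as
  `engine = "reference"` and the test suite asserts exact equality of the
  two on randomized inputs.
- **Oracle.** `exhaustive_curve()` enumerates all `n!` orders (guarded at
  8 cells) using only the reference engine, giving exact means and
  extremes; sampled curves are validated against it, and in the
  all-specialist special case (every epiphyte on one host, where
  exclusivity reduces to richness) against `vegan::specaccum(method =
  "exact")`.
- **Sampling.** Orders are drawn uniformly and independently; duplicate
  orders across draws are allowed, as in standard accumulation-curve
  practice. The alternative (rejection of duplicates) changes nothing
  detectable at realistic cell counts and complicates the estimator.
- **Seeds.** One master seed; each scope (area or regional) derives its
  own stream as `master + hash(label) mod 2^31 - 1`, so adding an area
  never perturbs another area's curve.
- **Monte-Carlo caveat.** A sampled mean with `n_perm` draws carries
  standard error `sd/sqrt(n_perm)` at every step; any validation that
  checks many steps against an exact oracle at a fixed multiple of that
  standard error will fail some steps by chance at the corresponding tail
  rate. Envelope checks are one-sided and exact (sampled extremes can
  never exceed exhaustive extremes) and so are free of this.

Curves are emitted as tables (`step`, `mean`, `min`, `max`);
`plot.accumulation_curve()` draws the conventional figure (solid mean,
dashed envelopes) as a thin layer over the table.

## Venn partitions of a focal host's flora

`venn_partition()` classifies every species recorded on a focal host by
the exact set of listed areas where an (epiphyte, focal host) record
exists. Classes are disjoint, cover the host's flora in those areas, and
depend only on (epiphyte, host, area) support — cell-level detail and
record duplication cannot move a species between classes. Exclusivity here
is relative to the focal host and the listed areas: a species in a
single-area class may occur on other hosts anywhere. Output is tabular
(all `2^k - 1` membership classes, empty ones included, guarded at 10
areas); drawing a six-set Venn is out of scope.

## The simulator: what it emulates and what it does not

`simulate_occurrences()` generates datasets with the statistical structure
the analysis assumes, plus the truth needed to check recovery:

| parameter | default | rationale |
|---|---|---|
| `n_lichens`, `n_hosts`, `n_cells`, `n_areas` | 700, 70, 480, 6 | the shape of a large regional compilation: hundreds of epiphytes, tens of hosts, a few hundred 10 km cells, a handful of areas |
| `p_specialist` | 0.25 | a quarter of species truly single-host, matching regional exclusivity levels reported for Mediterranean epiphyte floras |
| `breadth_prob` | 0.1 | truncated geometric on {2..n_hosts}: most generalists use few hosts, the tail reaches ranges of ~40–50 — the widest ranges seen in such compilations |
| `occupancy_range` | (0.01, 0.45) | per-host cell occupancy drawn uniformly: rare shrubs up to a dominant host occupying just under half the cells |
| `p_detect` | 0.3 | per (epiphyte, host, cell) detection where a niche host is present; compiled surveys are far from exhaustive |

Areas are contiguous, near-even blocks of cell indices — sufficient
because no statistic in the package uses geometry. Detection is
independent per (epiphyte, host, cell): there is **no spatial
autocorrelation, no climate covariate, and no area-level host turnover**.
Consequently simulated local communities are statistically exchangeable
subsets of the regional pool, and local exclusivity percentages sit close
to the pooled one. Real data behave differently (local percentages well
above regional, strong area-exclusive floras on widespread hosts), driven
by exactly the mechanisms the simulator omits. Passing tests therefore
demonstrate that the *statistics* are computed correctly and that
parameter recovery works — not that the generator reproduces regional
floristics.

Two recovery facts anchor the validation. With complete detection
(`p_detect = 1`, every host occupying at least one cell), apparent pooled
exclusivity equals the realized specialist fraction exactly — generalist
niches are fully revealed, specialists cannot gain hosts. With imperfect
detection, subsampling cells pulls in two directions: generalist masking
(unseen second hosts) inflates the exclusive share, while the loss of
sparsely recorded species — which are exclusive by construction even at
full sampling — deflates it. At extreme undersampling (a single cell)
masking dominates overwhelmingly; at moderate subsampling of a
well-detected dataset the dropout term can slightly outweigh it, dipping
the apparent percentage below the full-grid value before both converge.
The apparent exclusivity fraction is thus *not* monotone in sampling
effort in general, although the exclusivity *count* still rises to its
asymptote as in the accumulation curves.

## Problem sizes used in the shipped checks

The test suite validates sampled curves against exhaustive enumeration on
randomized cubes of up to 6 cells (where `6! = 720` orders are cheap), and
exercises recovery on simulations at the default study shape above;
`scripts/acceptance.R` runs one full pipeline pass at those defaults (a
few tens of seconds). These sizes are the package's own choice of
demonstration scale: large enough that curve asymptotes and recovery are
visible, small enough to run routinely.

## Known limitations

- Opaque taxonomy: synonymy and genus-level records are the user's
  problem; exclusivity is label-exclusivity.
- Presence-only: a host visited once and a host surveyed exhaustively
  weigh the same; `n_cells` per host in `host_table()` is the only effort
  proxy exposed.
- No inferential machinery: the package computes the descriptive
  statistics and their resampling envelopes, not null-model tests of
  preference strength.
- The simulator's independence assumptions (above) make it a correctness
  harness, not a fitted model of any real landscape.
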
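---
title: "Exploring assembled metagenomes with contigscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring assembled metagenomes with contigscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contigscape)
```

# The problem

Shotgun metagenome assemblies mix contigs from many organisms at widely
different abundances. The canonical exploratory view plots each contig in
the GC × coverage plane — contigs from one genome share GC content and
read depth, so taxonomic assignments can be corroborated visually and
genome bins delimited by eye — with point size tracking contig length and
color tracking taxonomy. `contigscape` provides the computational core of
that workflow as plain functions: every stage (ingestion, taxonomy
collapse, search, filtering, gating, styling, plot building, export) is a
pure function from data to data, and the interactive HTML view is just a
renderer for a declarative specification that can be tested without a
browser.

# Data model

A dataset couples a typed contig table with optional sequences and
annotations. Table columns carry a *kind* (`numeric` if every non-missing
cell parses as a real number — scientific notation included, thousands
separators rejected for deterministic parsing — else `ordinal`) and a
*role*. Exactly one column is the contig `id`; `x`, `y`, `size` and
`color` designate plot properties; every numeric column not used as a plot
property automatically becomes a `filter` parameter, and everything else
is `info`. Missing cells are explicit `NA`s: they are excluded from filter
ranges, from value binning, and they fail every range filter
(conservative exclusion, so a filtered view never silently includes a
contig whose value is unknown).

GC content is defined as (G+C)/(A+C+G+T), case-insensitive, with N and
IUPAC ambiguity codes excluded from the denominator — this avoids biasing
GC on gappy contigs — and is undefined (NA) when a sequence has no
unambiguous base. When a metadata table lacks length/GC columns they can
be filled from attached sequences (`add_sequence_stats()`).

Annotations use GFF3 (1-based inclusive coordinates, nine tab-separated
columns); all `key=value` attribute pairs are preserved in order, with
standard percent-escaping applied on write and removed on read, which is
what makes the GFF export→import round trip exact. Parsing errors carry
the offending line number. Attaching components cross-validates them:
sequences for unknown contigs are an error; annotation features on
unknown contigs are dropped with a counted warning (so a valid dataset
always satisfies its referential invariants).

# Taxonomy collapse

Complete-lineage strings ("root-first, `;`-separated") are parsed
positionally — no rank-name validation against a reference taxonomy, since
real pipelines emit heterogeneous lineage text. The distinct lineage
prefixes form a tree whose node weights are contig counts.

Legends cannot show hundreds of species, so the tree is collapsed to at
most `k_max` groups (default 30, matching the 25–30-group legends that
work well in practice) by greedy frontier refinement:

1. the frontier starts at the root;
2. repeatedly, the frontier node with the largest contig count that has at
   least one unexpanded child is replaced by its children, *provided* the
   resulting frontier size stays ≤ `k_max` (ties broken by lexicographic
   node name, making the result deterministic);
3. a node at which some contigs' lineages terminate is retained alongside
   its children — otherwise those contigs would lose their only selected
   ancestor;
4. refinement stops when no expansion fits.

Each classified contig is assigned to its deepest selected ancestor;
contigs with empty lineages go to a reserved `Unclassified` group (they
must remain plottable rather than vanish). The result always covers every
contig, respects the cap, and is *maximal*: no remaining node can be
expanded without exceeding `k_max`. Count-weighting (rather than length-
or leaf-weighting) was chosen so that the legend resolves the taxa that
dominate the picture the user actually sees.

The test suite verifies cover/bound/maximality against an exhaustive
enumeration of all reachable frontiers on random trees. One property that
does *not* hold in general is depth monotonicity in `k_max`: when
expansion sizes differ, a larger cap can admit one large expansion that
blocks several smaller ones, and the count-weighted mean assignment depth
can dip. It provably holds when every refinement step grows the frontier
by exactly one node (e.g. uniformly binary trees), and it is asserted in
exactly that regime.

# Search, filters, and gates

Search is a case-insensitive plain-substring scan (regular expressions
behind an explicit flag, so a Pfam accession is never accidentally a
pattern) over the text rendering of *every* metadata field — numeric
values match their canonical text form, so searching `3051` finds a
coverage value — plus annotation feature types and attribute values. The
per-contig hit count is the number of matching fields plus the number of
matching features; group summaries aggregate hits through the partition
and conserve totals exactly.

Range filters are inclusive on both ends and conjunctive. Genome-bin
gates are axis-aligned rectangles in the GC × coverage plane, applied in
list order with first-match-wins overlap resolution; every contig gets
exactly one label (`unbinned` when nothing matches or a value is
missing). No automatic clustering is attempted — gating expresses the
analyst's visual bin boundaries, and dedicated binning tools exist for
the automated problem.

# Color

Three modes, all deterministic: ordinal labels cycle through a fixed
20-color qualitative palette; quantitative columns are either binned —
equal-frequency bins by default, with interior edges at the
nearest-rank `j·n/k` order statistics, because coverage distributions are
heavy-tailed and equal-width bins would put almost everything in one bin
(equal-width is available as an option) — or mapped along a linear
two-color gradient over the observed range, with the minimum and maximum
mapping exactly to the endpoint colors and constant columns mapping to
the low color.

# Plot and track specifications

`build_plot_spec()` produces a declarative object, not pixels. Mark
*area* is proportional to the size value (the perceptually standard
choice for bubble plots): radius = `r_min + (r_max − r_min)·sqrt(v/v_max)`
with display-unit clamps `r_min = 2`, `r_max = 40`. Coverage axes default
to log10 in the CLI (abundance spans orders of magnitude); GC axes are
linear. Non-positive values on a log axis are dropped with a count rather
than offset — offsetting would silently distort positions. The spec
carries an exact audit of every contig:
`marks + filtered_out + hidden + dropped_log = total`, an invariant the
tests check across randomized configurations. Search hits are flagged
`outlined` (rendered as black-ringed circles); hover fields carry all
info/filter columns, including the complete lineage.

Contig tracks collect a contig's features overlapping a window (inclusive
overlap test), assign lanes greedily in start order so overlapping glyphs
never share a lane, and orient glyphs by strand (`.` draws forward).

`render_html()` writes a single self-contained document: the
specification is embedded as a JSON payload block and drawn by a small
dependency-free SVG viewer with hover tooltips, wheel zoom, and drag
panning. The tested contract is the payload — byte-identical across
re-renders of the same spec — not the rendering.

# The synthetic-assembly generator

`generate_assembly()` emulates the structure of a real community
assembly: per-genome log-normal contig lengths and coverages (assemblies
are heavy-tailed: many short contigs, few long ones), per-contig GC drawn
from a truncated normal around the genome mean and realized base by base,
lineages copied from the model, and CDS gene models (300–1500 bp,
alternating strands) tiled along each contig with Pfam-shaped attribute
tokens. Planted token families (`PF` + 5 digits, disjoint from the
background pool so searches are unambiguous) are written onto known
carrier contigs with known per-carrier feature counts, giving exact
ground truth for search recovery. Everything is driven by R's seeded
integer-state generator, so a fixed seed reproduces the output exactly.

`demo_assembly()` is a canned desk-scale community: six archaeal genomes
(50 contigs each, ~8 kb median length) at well-separated GC/coverage
centroids (GC 0.34–0.66, coverage 30–300×, SDs 0.012 and 0.15 log units),
60 short low-coverage unclassified background contigs, one 44 kb contig
at ~3051× coverage standing in for an over-represented mobile element,
and seven planted token families with both single- and multi-hit
carriers. Gates at ±3 SD around the true centroids recover ~97–98% of
contigs; the residual misses come from the GC base-sampling noise on
shorter contigs (binomial SD ≈ `sqrt(p(1−p)/L)` adds to the planted
spread), which is also why the demo genomes use ~8 kb contigs rather
than ~1 kb ones.

What the generator does *not* emulate: sequence homology between genomes,
chimeric contigs, strain-level coverage mixtures, or GC–coverage
correlation. Passing tests therefore demonstrate correctness of the
operations on structurally realistic inputs, not robustness to every
pathology of real assemblies.

`taxonomy_survey_models()` provides the companion taxonomy stress
fixture: 2 domains × 3 phyla × 4 genera × 5 species = 120 species-level
lineages, two contigs each (500 bp — sequence content is irrelevant
here). Collapsing its tree at the default cap of 30 lands at 28 groups:
after the 24 genera are on the frontier, exactly one can expand into its
5 species before the cap blocks everything — a deterministic outcome of
the tree shape, independent of the seed.

# Problem sizes and numerical choices

The shipped fixtures are desk-scale by design: the demo community is 361
contigs (~2.8 Mb of sequence, ~2.9 k features) and the survey is 240
contigs, which keeps the full test suite under a minute while leaving
every statistical check comfortably powered (e.g. per-genome empirical GC
within 0.03 of the model mean at n = 50). Delimiter auto-detection counts
tabs vs commas in the header and refuses ties rather than guessing.
Numeric export uses R's shortest round-trip rendering, so CSV
export→ingest is exact to the bit. Quantile bin edges are deduplicated
(repeated values can merge bins); a constant column yields a single bin
and, under gradient coloring, the low endpoint.

# Limitations

* Search is substring-based; there is no fuzzy matching or tokenization.
* Gates are rectangles — deliberately manual; no tetranucleotide or
  coverage clustering.
* The taxonomy collapse optimizes a greedy refinement, not a global
  deepest-frontier objective; maximality is guaranteed, global optimality
  is not.
* Coverage is taken as a metadata column; the package does not compute it
  from read alignments.
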
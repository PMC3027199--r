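---
title: "Methods: haplogroup classification, median-joining networks and rho dating in mtlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplogroup classification, median-joining networks and rho dating in mtlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlineage)
```

# Scope

`mtlineage` implements the computational core of a classical human-mtDNA
phylogeographic study: scoring variants against the revised Cambridge
Reference Sequence (rCRS), screening and assigning samples to haplogroup
M9a'b lineages by diagnostic motifs, building median-joining networks of
condensed haplotypes, and converting the ρ statistic and its heuristic
standard error σ into coalescence ages under calibrated molecular clocks.
A seeded simulation layer generates genealogies and population surveys with
known ground truth, so every stage is testable without any external data.

# Variant model

Variants are recorded in the field's position-based nomenclature relative to
the rCRS (16,569 bp, 1-based, closed intervals throughout):

* a bare position (`16234`) is a transition;
* a trailing base (`16265C`) annotates a transversion — when a reference is
  supplied the base is re-resolved against the reference's purine/pyrimidine
  class, and tokens resolving to transitions are canonicalized back to the
  bare form;
* `249d` deletes the base at 249; `5899+C` inserts C after 5899 (multi-base
  insertions are a single variant anchored to the nearest reference position
  5' of the gap);
* `@16291` marks a back mutation (reversion to the reference state);
* trailing `R`/`Y` mark A/G and C/T heteroplasmies. Heteroplasmic variants
  are stored with a flag: they are retained for display and network states
  but never enter dating counts.

`score_against_reference()` converts a gapped alignment row into this
representation; parsing and formatting are exact inverses, which the test
suite checks by fuzzing the full grammar.

## Masking

Following standard practice for control-region data, the default mask
(`default_mask()`) disregards the hypermutable transition at 16519 and the
C-stretch length variation in 16180–16193 and 303–315. Only insertions and
deletions are removed inside those windows: a point transition there (e.g. at
16189) is a legitimate clock character and is retained. The exact published
rules for C-stretch handling are not fully reproducible from the text, so
this indel-only reading is the package's documented approximation. Masking is
idempotent and never adds variants.

The potentially pathogenic transition at 11778 is additionally excluded from
dating by default (`date_clade(..., exclude_sites = 11778)`); the list is a
plain argument, so other sites can be excluded the same way.

# Haplogroup classification

A nomenclature is a rooted tree whose nodes carry defining variants relative
to their parent (`load_definitions()`, tab-indented text format). The default
fixture encodes the published M9a'b update: M9a = 14308 + 16234,
M9a1 = 1041, M9a1a = 16316, M9a4 = 6366, M9a5 = 385 + 8155 + 12237, with the
coding diagnostic 4491 on M9b. Definers of the deeper branches (M9a1a1,
M9a1a2, M9a1b, M9a1b1, M9a1a1c, M9a1a1c1) are published only in tree figures;
the shipped file marks synthetic stand-ins for them, clearly commented, and
users are expected to edit the file to their nomenclature build. M9a'b itself
is a *structural* node (definers `-`): it is diagnosed by the candidate
screen, not by tree matching, and structural nodes are never assignment
targets.

The candidate screen (`screen_m9ab_candidate()`) follows the survey design:
a sample qualifies if it carries the full control-region motif
16223-16234-16362-153 and/or a transition at coding site 3394 or 4491.

`assign_haplogroup()` returns the deepest node whose cumulative motif (the
union of definers along the root path, with back mutations cancelling
earlier gains) is fully present. Matching is position-based for
substitutions because literature HVS-I data are plain position lists; indel
definers must match in kind. A declared back mutation `@P` in a profile both
satisfies a motif requirement at P (the lineage passed through the variant)
and cancels it when the definer itself is a reversion.

**Paragroup rule.** A sample that fully matches node X and carries *no*
defining variant of any child of X is a plain member of X. A sample carrying
partial-but-incomplete evidence for some child (say one of M9a5's three
definers) cannot be placed confidently below X and is reported in paragroup
form `X*`. A screen-positive sample matching no node at all is the focal
clade's paragroup (`M9a'b*`), mirroring the survey's 66 control-region-only
mtDNAs that could not be placed deeper. This is the one place the package
deviates from a literal reading of its design notes, which star the
*no-child-evidence* case instead; that reading is inconsistent both with the
worked examples it accompanies and with the field's use of `X*` for "member
of X, no named subclade", so the package implements the consistent rule.

Assignments resting solely on control-region definers (M9a1a's 16316) carry
a `control_region_only` flag, echoing the published caveat that such
definitions are weaker than coding-region ones.

`near_match_assign()` implements matching/near-matching against classified
lineages: distances are Hamming counts over the HVS-I window (16090–16365)
plus any explicitly supplied coding sites; identity inherits the label, a
unique nearest neighbour within `k` (default 1, one-step neighbours) donates
its label as `near_match`, and ties across labels fall back to the deepest
common ancestor in paragroup form — the conservative choice matching the
survey's fallback to `M9a'b*`. In the pipeline, near-matching is applied only
to literature-sourced profiles; study samples carry coding information and
keep their motif call.

# Median-joining networks

Profiles are condensed to haplotypes (`condense()`): state vectors over the
analyzed positions, `0` for the reference state, `1` for a transition, a base
letter for a transversion, `d`/`+S` for indels and `R`/`Y` for
heteroplasmies. Identical vectors merge, summing counts and per-region
tallies; output order is lexicographic in the state vector so ids are
reproducible. Distances are weighted mismatch counts with a uniform default
weight of 10 per position — the cited network software's convention; the
published analysis does not state its run parameters, so epsilon defaults
to 0 and weights are configurable.

`minimum_spanning_network()` processes distance classes in increasing order
and, within a class, keeps *every* link joining components that were
distinct at the start of the step (not one link per merge), so all equally
short alternative connections survive; the result contains every minimum
spanning tree.

`median_joining()` alternates two phases and then prunes:

1. **Median generation.** For node triples of the current set, the
   per-position majority vector is computed; positions where all three
   states differ (possible only for multi-state characters) expand into
   quasi-medians, retained when they strictly reduce the triple's connection
   cost. Majority medians of three distinct vectors always do, so generation
   runs to the (quasi-)median closure. "Triples connectable in the network"
   is read as triples within one connected component — the MSN is always
   connected, so all current triples participate. This makes the constructed
   object independent of iteration order and exactly enumerable by brute
   force, which is how the test suite checks it: on all fuzzed instances
   with ≤ 5 haplotypes over ≤ 6 binary sites, the result equals an
   independent exhaustive-enumeration oracle.
2. **Relaxed MSN.** The epsilon-relaxed minimum spanning network is built
   over the closed node set.
3. **Relevance pruning.** Unobserved nodes of degree ≤ 2 that lie on no
   shortest connection between observed haplotypes (in the weighted state
   metric) are removed in batches, rebuilding the network after each batch,
   to a fixed point. Batch removal keeps the result order-independent.

Median nodes are labelled `mv1`, `mv2`, ... after canonical sorting, so
outputs are byte-reproducible under input permutation. Note two properties
that this construction deliberately does *not* have: because degree-2
medians **on** shortest connections are retained, equal-length parallel
geodesic paths survive, and the network's total link length may exceed that
of the observed-only MSN; the network contains a minimum spanning tree of
its final node set, which is the meaningful guarantee once medians
intervene. An iteration cap (default 100 rounds) and a node cap (default
2000) guard against pathological inputs; quasi-median closures can grow
exponentially in the worst case, which is inherent to the method, not a
tuning knob.

# Rho dating

For a rooted genealogy whose links carry mutation counts $m_l$ and whose
tips carry sampling multiplicities (total $n$),

$$\rho = \frac{1}{n}\sum_l m_l\, n_l, \qquad
  \sigma = \sqrt{\frac{1}{n^2}\sum_l n_l^2\, m_l},$$

where $n_l$ is the number of sampled lineages below link $l$. The first is
the average mutational distance of samples to the root; the second is the
standard heuristic error under a Poisson mutation model (the published
analysis cites it without printing the formula; on a star genealogy with
$k$ mutations per branch it reduces to $\sigma = \sqrt{k/n}$, consistent
with the published table's magnitudes). Both are invariant to tip
relabelling and to expanding a multiplicity-$c$ tip into $c$ identical tips;
the implementation computes the link-sum form and is cross-checked against
an independent per-tip path-walk oracle on fuzzed genealogies.

A linear clock converts exactly: $T = \rho \cdot r$, $\Delta T = \sigma
\cdot r$ years per accepted mutation. The built-in `hvsi_clock()` uses
18,845 years per transition in 16090–16365 and counts only masked,
non-heteroplasmic transitions inside that window. Whole-genome and
synonymous-mutation calibrations — which in the source analysis rest on a
purifying-selection correction curve and a synonymous rate constant not
printed there — are deliberately **not** hard-coded: `linear_clock()` takes
any user-supplied rate, and `custom_clock()` accepts an arbitrary
ρ→years conversion (e.g. an interpolated table) with
$\Delta T = \mathrm{convert}(\rho + \sigma) - \mathrm{convert}(\rho)$.
Ages are stored in years and displayed as kiloyears rounded half-up to one
decimal, the convention of published age tables. At that rounding, the
printed HVS-I ages regenerate exactly from the printed ρ/σ for most clades;
for a few rows (e.g. ρ = 0.55 → 10.4 vs a printed 10.5) the published value
reflects unrounded internal digits, and the tests assert agreement within
0.2 ky there.

`date_clade()` applies the clock's mutation filter per link (all accepted
variants, synonymous only via the gene-table annotator, or HVS-I window
transitions), after dropping heteroplasmies, explicitly excluded sites and
masked variants. On genealogy links, a declared back mutation is a real
mutational event and is counted; in *profile-level* HVS-I summaries
(`count_hvsi_transitions()`), `@P` is bookkeeping relative to the reference
and is excluded. `genealogy_from_profiles()` builds the standard star
construction around a designated ancestral haplotype — each sample a pendant
tip carrying its mutational differences from the root type, losses recorded
as back mutations — which is how control-region founder ages are computed in
practice.

Functional-effect annotation (`classify_functional_effect()`) translates
protein-region substitutions in the record's frame with the vertebrate
mitochondrial genetic code (Biostrings table 2) and compares amino acids;
tRNA/rRNA/control positions return their feature type and indels return
`indel`. The gene table is a user-supplied TSV; none is bundled, since a
full mtDNA annotation is an external fixture, not package data.

# Synthetic data: the stated world

`simulate_star_genealogy()` draws, per lineage, $K \sim
\mathrm{Poisson}(\mathrm{TMRCA} \times \text{rate})$ mutations at positions
sampled without replacement from the position pool (default: the HVS-I
window), i.e. infinite-sites behaviour with homoplasy off. Defaults are the
conditions of the recovery experiment the package tests: TMRCA 20,000 years
— inside the post-glacial window the source analysis is about — at the
HVS-I transition rate 1/18,845 per year, with `ts_tv_ratio = Inf` because
the transition clock's world is pure transitions; a finite ratio is
available for stress tests. Under these defaults, 200 replicates of n = 50
lineages recover the true age within 5% in the mean, with ≥ 90% coverage by
$T \pm 1.96\,\Delta T$.

`simulate_coalescent_genealogy()` uses the standard neutral coalescent with
exponential waiting times at rate $\binom{k}{2}/\theta$, so `tmrca_years`
is the expected *pairwise* coalescence time (for n = 2 the expected TMRCA
equals it exactly — the closed form the tests check). Mutations are Poisson
on branch durations; sites are drawn without replacement tree-wide, so tip
profiles reconstruct exactly from the genealogy.

`simulate_population_survey()` draws multinomial regional samples across
configured haplogroup frequencies; carriers receive their haplogroup's
cumulative motif plus the clade's shared control-region sites (153, 16223,
16362 for all M9a'b members) and Poisson private mutations; basal M9a'b
carriers additionally receive 16234, so they present the full screen motif
with no subclade information — the synthetic analogue of the survey's
unassignable control-region-only samples. Background (non-carrier) profiles
draw variants from a pool that, with homoplasy off, excludes every definer
and screen-diagnostic position, so the screen accepts exactly the spiked
carriers and motif assignment recovers 100% of true labels — a closed loop,
not a statistical claim. What a green closed loop does **not** establish:
robustness to homoplasy, recurrent mutation, phantom mutations or
heteroplasmy miscalls in real surveys; the `homoplasy = TRUE` toggle exists
precisely to break the loop for stress testing. All simulator randomness
flows through one seed, and identical configurations produce identical
datasets byte for byte.

# Pipeline and formats

`run_pipeline()` chains mask → screen → classify (with the literature-only
near-matching fallback) → condense → median-joining network → star-rooted
HVS-I dating of the focal clade → frequency tabulation, writing each
artifact as headered TSV (or the documented network text format) plus a run
log with the configuration hash and seed; reruns with an identical
configuration are byte-identical, and every artifact re-parses with the
package's own readers. Configuration files use base R's DCF format (one
`Field: value` per line) because the R stack here has no YAML parser; the
format round-trips through `save_pipeline_config()`/`load_pipeline_config()`.
A thin command-line wrapper over these exported functions ships in
`inst/scripts/mtlineage-cli.R`; the functions themselves are the supported
interface.

# Numerical and design choices, in brief

* Coordinates: 1-based rCRS positions, closed intervals everywhere.
* Unassigned/structural nodes: a nomenclature node may be declared
  structural (`-`), organising the tree without being a match target.
* The 3394 screen diagnostic is not a tree definer: the published text ties
  it to candidate screening, and placing it on M9a'b or M9a would contradict
  the published worked assignments; 4491 sits on M9b, consistent with the
  "and/or" screen phrasing.
* Tie-breaking in assignment (same depth, both fully matched — possible only
  with homoplasic input) prefers the larger cumulative motif, then
  lexicographic order, for determinism.
* Rounding: display-level only, half-up, one decimal kiloyear; all stored
  values are unrounded doubles.
* `quasi_medians()` caps tie expansion at 64 combinations per triple and the
  network at 2000 nodes; both are error conditions, not silent truncations.
* The synthetic reference (`synthetic_reference()`) is a seeded random
  16,569-base surrogate used where only coordinates and base classes matter;
  it is labelled synthetic and is not the rCRS.

# Known limitations

* The median-joining implementation runs median generation to closure, which
  is exact (and oracle-checked) on the small, low-homoplasy instances this
  package targets, but can be expensive on large highly reticulate data sets
  where the cited heuristic's greedy median selection would scale better.
* Whole-genome and synonymous-clock ages from the source analysis are not
  reproducible here by design: they require a correction curve and rate
  constant published elsewhere, supported only as user-supplied clocks.
* The near-matching protocol of the cited convention is not fully specified
  in the source; the one-step-neighbour default and the common-ancestor tie
  rule are this package's documented choices.
* No alignment is performed: inputs must already be in rCRS coordinates.
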
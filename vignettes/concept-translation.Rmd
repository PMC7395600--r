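---
title: "Translating taxon concepts between monitoring-program checklists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating taxon concepts between monitoring-program checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxobridge)
```

## The problem

Long-running biodiversity monitoring programs (Pollard-walk butterfly
transects are the motivating case) each survey under their own stable
species checklist. The same name string on two checklists can denote
different *taxon concepts* — circumscribed biological entities — because
the programs follow different taxonomic authorities, and the same concept
can hide behind different names. Pooling count data across programs by
naive string matching therefore manufactures spurious zeros and merges
non-equivalent taxa, which biases any multi-program trend analysis.

taxobridge encodes a curation system that fixes this without asking any
program to change its list. Every program declares one comprehensive
authority (its *base list*) whose reading of the names it most closely
follows. Base-list entries (*holders*) in turn link to a master
*switchboard* of fine-grained concept nodes — the finest granularity any
authority distinguishes. All of this lives in one Darwin Core Taxon style
CSV (`taxonID`, `parentNameUsageID`, `scientificName`, `taxonRank`,
`datasetName`, `conceptNote`), so a record's chain
program → base holder → switchboard concept is an ordinary parent/child
walk.

Two ideas make the graph expressive enough:

* **Duplicated holders.** When an authority files several separable taxa
  under one name, its base list carries one holder per concept, all
  sharing the name string. A program that distinguishes the taxa links
  each of its records to a distinct holder, so program-level granularity
  survives translation through a coarse authority.
* **Occurrence vs. interpretation.** Each program name has two concept
  sets. Its *occurrence set* (`concepts_of()`) is the upward closure of
  its records: the concepts the program actually monitors under that name
  within its range. Its *interpretation set* (`interpretation_of()`) is
  what the program *means* by the name: the closure over all same-named
  holders in its base list (a broad authority's "Celastrina ladon" means
  every azure it files under that name), never smaller than the occurrence
  set. Donors supply data from their occurrence sets; receivers ask in
  terms of their interpretation. The two differ exactly when authorities
  lump, and that difference is why requests are not symmetric: a program
  can legitimately accept data recorded under finer concepts it does not
  separate, while the reverse request must come back empty.

## The translation algorithm

`translate(mapping, receiver, name, donor)` ascends from the receiver's
record(s) to the switchboard and descends into the donor's checklist
through the donor's declared base. Writing `R` for the receiver name's
interpretation set (minus concepts the receiver monitors under *other*
names — a name does not claim what its siblings already track, but always
including its own occurrence set) and `O(d)` for each donor name's
occurrence set, each donor name is classified:

* no overlap with `R` — irrelevant;
* `O(d)` inside `R`, not spilling onto other receiver names — a clean
  candidate;
* `O(d)` spilling onto concepts the receiver monitors under sibling
  names — the donor lumps relative to the receiver's own checklist;
  usable only in combination, a `CM+` candidate;
* `O(d)` containing concepts the receiver does not monitor at all — the
  donor's pooled records cannot be decomposed, so the name is unusable
  and contributes nothing.

The result is then: `Zero` (no usable donor name; the concept is presumed
absent from the donor's monitored range — a valid biological answer,
distinct from the hard error raised for a name that is not on the
receiver's checklist); `MM` with all names, sorted, when two or more
clean candidates split the request; `PM`/`CM` for a single clean
candidate (`PM` only when name, occurrence set and interpretation all
agree — same string under a different reading is still only compatible);
or `CM+` with `required_receiver_siblings` listing the receiver taxa
whose data must accompany the donor's lump.

Three flag channels accompany results. `MM` and `CM+` always carry a
complexity flag. Curated complexity notes (a `flag:` clause in
`conceptNote`) travel with every request touching the record — and, for
`Zero` results, with the donor's same-complex names, since "absent" inside
a disputed complex still deserves the caveat. An asymmetry flag is added
when the reverse request differs in kind; for `Zero` results the reverse
probe runs through donor names that overlapped the request but were
unusable.

## The curated fixture

`celastrina_fixture()` encodes the azure blues, the hardest case in the
ten-program network: seven switchboard concepts (*ladon*, *neglecta*,
*lucia*, *echo*, *humulus*, plus unmonitored *serotina* and *idella*),
one broad authority filing all seven under *Celastrina ladon* (seven
duplicated holders) and two splitting authorities, and ten programs
ranging from full lumpers (*C. ladon/neglecta* conglomerates) to full
splitters. `expected_celastrina_matrix()` is the curators' pre-built
compatibility matrix over all 126 ordered (receiver taxon, donor)
comparisons; `build_matrix()` + `compare_matrix()` certify that the
translator reproduces it cell-for-cell, flags included, and that exactly
one program pair (Orange County ↔ MPG Ranch, two echo-only checklists
that align one-to-one) goes unflagged.

Two curation decisions deserve explanation:

* **Orange County's trinomial.** The program records *C. ladon echo*
  under a splitting base that has no broad *ladon* name to widen through,
  yet its usage follows the older broad western reading of *C. ladon*.
  Its interpretation set cannot be derived from the graph, so the fixture
  carries an explicit `scope=ladon|lucia|echo` clause in `conceptNote` —
  the designated channel for circumscriptions that only a curator can
  state. Its occurrence set stays `{echo}`: that is all the program's
  range contains.
* **Expected flags.** Flag expectations are encoded at the pair level:
  every comparison in the complex is expected flagged except the two
  Orange County ↔ MPG requests, matching the curators' assessment that
  every other pairing involves disputed interpretations in at least one
  direction.

## Checklist alignment and the discrepancy typology

`align_checklists()` compares two checklists name-by-name and classifies
every difference into the field's six-type typology: genus deviation
(`G`), species-epithet deviation (`S`, subtyped promotion /
misdetermination / synonym / subspecies-use when curation or rank
structure says why), spelling variant (`L`), conglomerate (`C`),
unmatched taxon (`U`), with subfamily deviations (`F`) excluded from
program-level summaries because program lists hang below the subfamily
level. Pairing runs exact matches first, then curator-supplied pairs,
then heuristics: identical binomial with different subspecies use; same
genus with epithet edit distance ≤ 2 *and* an identical two-character
prefix (the spelling rule — anything farther is proposed only as an
*unresolved* `S`, because certifying a synonymy is a curator's call, not
an algorithm's); same epithet under a different genus; conglomerates
matched to their split components. Ties are never broken silently: a name
with several equally close candidates is reported in `ambiguous` and left
unmatched. `summarize_alignment()` reports per-type counts and the total
as a percentage of the larger list (one decimal).

## The synthetic generator

`synthesize(synthetic_spec(...))` builds networks with known ground
truth: a switchboard of pronounceable syllable-alphabet concepts grouped
into genus complexes, base lists that file eligible congeneric pairs
under one duplicated-holder name with probability `lump_rate`, and
program checklists derived from their base with at most one injected
discrepancy per name (`G`, `S`, `L`, `U`, `C` at the stated rates).
Defaults (40 concepts, 3 bases, 10 programs, per-name rates of 1–2%)
mirror a realistic regional network, where program-vs-base deviation
loads of a few percent are typical. Design details that make ground truth
exact: injections are mutually exclusive per name; spelling injections
double the final letter (edit distance 1, prefix intact) and synonym
epithets come from a disjoint syllable alphabet, so the two can never
collide; every injection is logged, and expected match types are derived
by a set-relation enumeration over the generator's own bookkeeping —
independent of the mapping graph the translator walks.

What the generator does *not* emulate: geographic ranges (occurrence is
purely whether a program links a holder), subspecies hierarchies below
holders, interpretation deviations of the Orange County kind (synthetic
programs mean exactly what they monitor), and correlated or compound
discrepancies. Green synthetic tests therefore certify the set algebra
and bookkeeping, not the curation judgement real checklists need.

## Numerical and testing choices

Everything is deterministic: no tolerance parameters exist anywhere;
multiple matches are returned alphabetically; the generator derives all
randomness from its single seed and restores the caller's RNG state.
The test suite exercises, among other things, metric axioms of the edit
distance against a dynamic-programming oracle, losslessness of the
mapping-file round trip, exact recovery of injected discrepancy counts,
agreement of the translator with the set-relation oracle, and the
occurrence-level lump/split duality — a multiple match that splits a
receiver's own monitored concepts must invert to `CM+` for every returned
donor name. Property checks run over 1,000 seeded networks kept small
(6 concepts, 2 bases, 2 programs) so the full suite stays fast; the
public defaults are larger.

The duality property is deliberately stated at the occurrence level:
interpretation-driven multiple matches (a broad-authority receiver
collecting finer western taxa it never sees at home) invert to `Zero`,
not `CM+` — the donor of the broad data monitors none of the fine
concepts within its own range. That asymmetry is correct behaviour, not a
bug, and is exactly what the occurrence/interpretation split exists to
express.

## Limitations

Third-party receivers (a user with their own taxonomy, member of no
program) are out of scope, as is automatic synonym discovery from
external nomenclators and any use of explicit range polygons. The
interpretation closure covers names that appear in the base list; deviant
usages invisible to the base (broad trinomials, historical readings)
need a curated `scope=` clause. A full subspecies-level alignment of the
authorities' catalogues is likewise out of scope: holders live at the
finest level any base list distinguishes for the complexes under
curation.
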
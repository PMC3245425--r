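---
title: "Persistent identifiers for changing taxon concepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent identifiers for changing taxon concepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxcat)
```

## The problem

A taxonomic checklist names species, but a scientific name is not a stable
handle for a *concept*. Two editions of the same catalogue may use one name
for different circumscriptions (the set of organisms the name is meant to
cover), and two names for the same circumscription. The classic pattern is
the lump: a species accepted in one edition is demoted to a variety of
another species in the next, its old name surviving only as a synonym, with
the mapping running the opposite way when the concepts are split again.
Anyone attaching data to species — occurrence records, trait tables,
medicinal properties — needs to know whether "the same name" still means the
same thing.

`taxcat` implements the machinery a catalogue needs to manage this:

1. a checklist model with a Darwin-Core-style delimited reader;
2. versioned Life Science Identifiers (LSIDs) whose object part is a UUID
   and whose version part is an edition token, so an unchanged concept keeps
   its UUID across editions and only the version advances;
3. a change detector (the matcher) that decides, for every taxon of a new
   edition, whether it is the same concept as one in the previous edition;
4. a repository of typed concept relationships (congruence, inclusion,
   hierarchy) with the inference they license;
5. per-taxon TCS-style RDF/XML metadata documents and a local resolver;
6. a seeded synthetic-edition generator with ground-truth change logs.

## Concept signatures and the no-false-negative aim

The matcher does not attempt taxonomic judgement. For every taxon it builds
a canonical string over exactly the fields whose change is treated as
evidence of concept change — for species and infraspecific taxa the accepted
scientific name, all synonyms, all vernacular names, the geographical
distribution text and the identifier assigned by the data provider; for taxa
above species rank, where most of those fields are absent, the accepted name
plus the names of the higher taxa above it. Records pair exactly when their
canonical strings are identical.

The guiding asymmetry is that a *false negative* (a changed concept silently
keeping its identifier) is worse than a *false positive* (an unchanged
concept getting a fresh identifier). The encoding is therefore built to be
injective over field tuples:

* fields are joined with the unit separator (U+001F) and values inside
  multi-value fields with the record separator (U+001E), characters that
  cannot survive the whitespace normalization and hence cannot occur in
  data; absent fields stay in position as empty strings;
* multi-value fields are sorted (C locale) and de-duplicated, so input order
  can never masquerade as change;
* names are normalized to Unicode NFC with internal whitespace collapsed,
  but case is preserved — capitalization carries nomenclatural meaning;
* a SHA-256 digest of the canonical string is carried as an index, but
  pairing always confirms equality on the canonical string itself, so a
  digest collision cannot create a false pair.

Matching is the sort-adjacency algorithm: signatures of both editions are
pooled and sorted, and identical pairs are read off adjacent runs. This is
equivalent to the quadratic all-pairs comparison (the test suite checks the
equivalence against a brute-force oracle on seeded instances) at a fraction
of the cost. Identical signatures *within* one edition are reported as
ambiguous groups and never paired: silently picking one of two
indistinguishable records could transfer an identifier to the wrong concept.

Two deliberate consequences of the field list are worth knowing. Children do
not enter a species' signature, so a species whose varieties change (but
whose own fields do not) is treated as unchanged — the lumped-in variety
itself appears as a new concept. And lineage enters only above species rank,
so moving a species to a new genus is detected only through its (renamed)
accepted name. Both mirror the field definitions above rather than being
accidents of implementation.

## Identifier assignment

`assign_lsids()` turns a match result into an identifier map: paired records
keep the old UUID with the version field set to the new edition token;
unmatched new records get freshly minted UUIDs; identifiers of concepts
absent from the new edition are listed as deprecated, never recycled, and
remain resolvable forever. Because identity is carried by the UUID alone,
`same_concept()` can compare two LSIDs without any resolution step.

UUIDs are random version-4-style identifiers drawn from a private, seeded
RNG stream (`lsid_minter()`). Seeding makes runs reproducible for testing
and auditing; the stream is isolated so minting never perturbs a user's
global random state. The minter refuses to reissue an id it has issued and
retries against a caller-supplied avoid list.

## Heuristics are opt-in

Strict matching flags a record whose synonym list merely grew. The
`synonym_add` rule in `apply_heuristics()` promotes such a pair back to
"unchanged" when every added synonym is novel — it occurs nowhere in the old
edition as an accepted name or synonym — on the reasoning that a newly
catalogued synonym for an otherwise untouched record is probably extra
information, not a changed circumscription. The rule is off by default,
promotions are logged with the triggering rule, and a synonym that does
occur elsewhere blocks promotion, since it may signal a lump. Ambiguous
promotions (one old record matching several candidates, or vice versa) are
never applied.

A second opt-in shortcut (`use_provider_guid` in `match_config()`) pairs
records ahead of signature comparison when both carry the same
provider-assigned taxon GUID from the same provider, trusting the provider's
own change tracking where it exists.

## Relationships and what they license

The relation repository stores typed, directed assertions between concept
identifiers: `IsParentTaxonOf`/`IsChildTaxonOf` (hierarchy),
`IsCongruentTo`, `Includes`/`IsIncludedIn`, `Overlaps` (set relations), and
`HasSynonym`/`HasVernacular` (name relations). Declared inverses are
derivable rather than stored twice, insertion is idempotent, and
self-referential set relations are rejected.

`propagate_applicability()` answers the question that motivates the whole
apparatus: if data were recorded against concept A, which other concepts do
they provably apply to? The closure follows containment (A included in B
means A's records apply to B) and congruence (in both directions, treated as
transitive for inference even though stored edges stay as asserted).
`Overlaps` is stored and exported but never contributes — overlap licenses
no record transfer. Rank hierarchy edges are likewise excluded: a
parent-child edge is a classification statement, not a circumscription
containment, and conflating the two would silently propagate species records
to genera. `congruence_classes()` partitions all known concepts into
connected components of the congruence graph.

## TCS metadata documents

`build_metadata_document()` renders one taxon as an RDF/XML document in TCS
vocabulary: a single core `TaxonConcept` carrying `rdf:about` equal to the
LSID, its one accepted name as a `TaxonName` with rank (and citation when
present), and one `hasRelationship`/`Relationship` entry per synonym,
vernacular name, parent, child and stored repository relation. A
provider-assigned *name* GUID is wrapped in an anonymous `TaxonConcept` (a
concept node with no name of its own) linked by `IsCongruentTo`, because a
relationship joins two concepts, not a concept and a name. Namespace URIs
are configurable via `tcs_config()` since the historical vocabulary URIs may
no longer resolve; the element and property names are what matters here.

Documents are generated on demand from the edition and repository — the
catalogue is never stored as one big TCS document. `resolve_local()`
resolves an LSID against a store of editions: an explicit version pins its
edition; a versionless LSID resolves to the newest edition containing the
UUID (and the returned core element carries that edition's fully versioned
LSID); a deprecated identifier resolves to its last edition's document,
enriched with stored relations to current concepts. "Unknown UUID" and
"known UUID under an unknown version" raise distinct error classes.

## The synthetic generator

`generate_edition()` emulates the shape of a real checklist extract: a
complete kingdom-to-species hierarchy, binomial-style names with authorship
built from syllable tables, synonyms, language-tagged vernacular names,
region-list distribution texts, per-record provider identifiers and
occasional varieties. Default rates (30% of species carry synonyms, 20%
vernaculars, 10% a variety, mean four species per genus) are round figures
chosen to exercise every compared field on a realistically sparse table.
Names are guaranteed unique within an edition so that ambiguous signature
groups arise only when a test constructs them deliberately.

`mutate_edition()` applies explicit concept changes (rename, synonym
add/remove, distribution edit, provider-id change, taxon add/remove, lump,
split) and returns, alongside the mutated edition, the exact set of source
records whose signature was affected. That ground truth is computed from the
mutation bookkeeping, not by running the matcher, so the invariant "the
matcher's unmatched-old set equals the ground-truth changed set" is a real
two-sided check. Lump follows the published pattern: the absorbed species
disappears and survives as a variety of the survivor carrying its old name
as a synonym (the survivor's own fields are untouched, matching the
observation that the matcher sees species fields, not children); split is
the inverse.

What the generator does *not* emulate: misspellings and near-duplicate
names, authorship reshuffles, provider schema quirks, or editions whose
provider changes wholesale between years (which in strict mode would flag
every species). Passing tests therefore demonstrate the correctness of the
change-detection contract, not robustness to dirty real-world data — fuzzy
name matching is explicitly out of scope.

## Numerical and design choices

* **Hash**: SHA-256; equality is confirmed on canonical strings, so the
  digest is an index, not an arbiter.
* **Sorting**: all order-sensitive operations sort with the radix method
  (C locale) for platform-independent determinism.
* **Rank order**: a fixed total order from kingdom to the infraspecific
  ranks (subspecies, variety, form share one level). Unknown rank strings
  are rejected, not guessed, because the species-level boundary decides
  which signature form applies.
* **Vernacular language tags**: stored, exported, but excluded from the
  signature by default (`include_vernacular_language`); a language-tag
  correction alone is unlikely to reflect concept change, and the choice is
  a config toggle.
* **Authority comparison**: case-insensitive (DNS names); all other LSID
  components compare case-sensitively, and parse/compose preserve input
  bytes exactly.
* **Degenerate inputs**: empty editions match trivially (everything minted
  fresh); single-record editions yield empty hierarchy relation sets;
  cyclic parent pointers are reported by `validate_edition()` rather than
  crashing the reader; cyclic inclusion graphs terminate in the closure.
* **Problem sizes in the shipped checks**: the behavioural suites run on
  editions of roughly 200–520 records, 20 matcher-vs-oracle replicates and
  100 random 50-node relation graphs — large enough to exercise collisions,
  duplicates and deep hierarchies, small enough to run routinely.

## A worked run

```{r worked}
e2008 <- paper_fixture("droseraceae_2008")
e2009 <- paper_fixture("droseraceae_2009")
m <- match_editions(e2008, e2009)
m
# the one concept of 2008 with no 2009 counterpart:
subset(e2008$taxa, record_id %in% m$unmatched_old)$scientific_name

minter <- lsid_minter(42)
map2008 <- stats::setNames(
  vapply(e2008$taxa$record_id,
         function(i) compose_lsid(lsid(mint_object_id(minter),
                                       version = "ac2008")),
         character(1)),
  e2008$taxa$record_id)
assignment <- assign_lsids(e2009, m, map2008, "ac2009", minter)
assignment
assignment$deprecated
```

## Limitations

The matcher detects change; it does not classify it. Distinguishing a lump
from a rename, or attaching `IsIncludedIn` assertions between an old and a
new concept automatically, requires editorial judgement or richer provider
data and is left to the relation repository's explicit assertions. Matching
is exact: a one-character spelling correction is a concept change in strict
mode, by design. And the resolver here is local — serving documents over the
LSID network protocol is out of scope.
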
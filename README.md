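# taxcat

Persistent identifiers and change detection for taxon concepts in
taxonomic checklists.

## The problem

Large species catalogues are published in editions, and between editions
taxonomic opinion moves: two species are lumped into one, a species is split
into varieties, synonym lists grow, distributions are revised. A scientific
name is therefore not a reliable handle for a *taxon concept* — the
circumscription a name is meant to cover — and anyone integrating
species-linked data (occurrence records, trait databases, biomedical
literature indexed by organism) needs identifiers that track concepts, not
spellings.

`taxcat` is an R toolkit for catalogue maintainers and biodiversity
informaticians that implements the full identifier life cycle:

* **Checklist model** — read and validate Darwin-Core-style delimited
  checklist tables (`read_checklist()`, `validate_edition()`), with synonym
  and vernacular rows folded into their accepted records.
* **LSIDs** — parse, compose and compare Life Science Identifiers of the
  form `urn:lsid:<authority>:<namespace>:<uuid>[:<edition>]`
  (`parse_lsid()`, `compose_lsid()`, `same_concept()`), and mint fresh
  UUID object ids from a seeded generator (`lsid_minter()`).
* **Taxon matcher** — detect concept change between two editions by exact
  comparison of per-taxon *concept signatures* (`match_editions()`), then
  carry identifiers forward (`assign_lsids()`): an unchanged concept keeps
  its UUID and only the version token advances; every detected change mints
  a fresh UUID; superseded identifiers are deprecated but never recycled.
* **Concept relations** — a repository of typed relationships
  (`IsCongruentTo`, `Includes`/`IsIncludedIn`, parent/child, …) with
  inference: which concepts do data recorded against concept A provably
  apply to (`propagate_applicability()`), and which identifiers denote the
  same circumscription (`congruence_classes()`).
* **TCS export** — per-taxon RDF/XML metadata documents in Taxon Concept
  Schema vocabulary (`build_metadata_document()`) and a local resolver over
  a store of editions (`resolve_local()`), including perpetual resolution of
  deprecated identifiers.
* **Fixtures** — a deterministic generator of synthetic editions with
  ground-truth change logs (`generate_edition()`, `mutate_edition()`), plus
  small hand-encoded worked examples (`paper_fixture()`).

## The core idea: concept signatures

For every species (and infraspecific taxon) a canonical string is built from
exactly the fields whose change counts as evidence of concept change:

```
accepted name  |  sorted synonyms  |  sorted vernaculars  |  distribution text  |  provider id
```

joined with unambiguous separator characters so the encoding is injective;
taxa above species rank use `(accepted name, lineage)` instead. Two records
pair if and only if their canonical strings are identical — equality is
confirmed on the strings themselves, with a SHA-256 digest used only as an
index. Matching is the sort-adjacency scan (pool both editions' signatures,
sort, read identical pairs off adjacent runs), provably equivalent to the
quadratic all-pairs comparison. The design goal is *no false negatives*: any
change in a compared field forces a fresh identifier, at the accepted price
of some false positives.

## A worked example

The package ships a reconstruction of a published lump: in the 2008 edition
of a Droseraceae extract, *Drosera tracyi* is a species; in 2009 it has been
absorbed into *Drosera filiformis* as var. *tracyi*, with the old name
surviving only as a synonym.

```r
library(taxcat)

e2008 <- paper_fixture("droseraceae_2008")
e2009 <- paper_fixture("droseraceae_2009")

m <- match_editions(e2008, e2009)
m
#> <match_result> 10 pair(s), 1 unmatched old, 6 unmatched new, 0 ambiguous group(s)

subset(e2008$taxa, record_id %in% m$unmatched_old)$scientific_name
#> [1] "Drosera tracyi Macfarl."
```

Ten concepts (the order, family, both shared genera, and the unchanged
species and varieties) are recognised across editions; the lumped species is
the single 2008 concept without a counterpart. The six 2009-only records are
the genuinely new concepts (the genera *Aldrovanda* and *Drosophyllum*,
their species, the new variety, and *D. rotundifolia* var. *comosa*).

Carrying the identifiers forward:

```r
minter <- lsid_minter(42)
map2008 <- stats::setNames(
  vapply(e2008$taxa$record_id,
         function(i) compose_lsid(lsid(mint_object_id(minter),
                                       version = "ac2008")),
         character(1)),
  e2008$taxa$record_id)

assignment <- assign_lsids(e2009, m, map2008, "ac2009", minter)
assignment
#> <lsid_assignment> 16 LSID(s) assigned, 1 deprecated

assignment$deprecated$lsid
#> [1] "urn:lsid:catalogueoflife.org:taxon:32541659-9740-463c-98cb-38a2cf4b7d4b:ac2008"
```

The unchanged genus *Dionaea* keeps its UUID — only the version advances —
so the two identifiers compare equal as concepts without any resolution:

```r
map2008[["d3"]]
#> "urn:lsid:catalogueoflife.org:taxon:a89f7c65-0cd4-46f9-9997-0a8c82ef0dde:ac2008"
assignment$new_lsids$lsid[assignment$new_lsids$record_id == "e5"]
#> "urn:lsid:catalogueoflife.org:taxon:a89f7c65-0cd4-46f9-9997-0a8c82ef0dde:ac2009"
same_concept(map2008[["d3"]],
             assignment$new_lsids$lsid[assignment$new_lsids$record_id == "e5"])
#> [1] TRUE
```

The deprecated *Drosera tracyi* identifier remains resolvable forever: a
store built with `lsid_store()` returns its 2008 document, enriched with any
stored relations to current concepts (e.g. `IsCongruentTo` the new
variety). See the vignette (`vignettes/concept-identifiers.Rmd`) for the
full model, the heuristics, and the design decisions.

A thin command-line wrapper is installed as `exec/taxcat`
(`taxcat validate`, `taxcat match`, `taxcat stats`, `taxcat synth`,
`taxcat lsid parse`).

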
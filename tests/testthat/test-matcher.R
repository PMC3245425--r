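# Concept signatures, edition matching, LSID assignment, heuristics and
# change statistics.

test_that("signatures encode exactly the compared fields", {
  ed <- tiny_edition()
  # record_id is not a compared field: two editions differing only in ids
  # give identical canonical strings
  renamed <- ed
  renamed$taxa$record_id <- paste0("x", renamed$taxa$record_id)
  renamed$taxa$parent_id <- ifelse(is.na(renamed$taxa$parent_id), NA,
                                   paste0("x", renamed$taxa$parent_id))
  s1 <- concept_signatures(ed)
  s2 <- concept_signatures(renamed)
  expect_identical(s1$canonical_string, s2$canonical_string)

  # one added synonym changes the digest
  plus <- ed
  i <- match("s2", plus$taxa$record_id)
  plus$taxa$synonyms[[i]] <- "Rosa nova Hort."
  expect_false(concept_signature(plus, "s2")$digest ==
                 concept_signature(ed, "s2")$digest)

  # synonym input order never matters
  perm <- ed
  j <- match("s1", perm$taxa$record_id)
  perm$taxa$synonyms[[j]] <- c("Rosa b", "Rosa a", "Rosa c")
  perm2 <- ed
  perm2$taxa$synonyms[[j]] <- c("Rosa c", "Rosa a", "Rosa b")
  expect_identical(concept_signature(perm, "s1")$canonical_string,
                   concept_signature(perm2, "s1")$canonical_string)

  # digest is the SHA-256 of the canonical string
  sig <- concept_signature(ed, "s1")
  expect_identical(sig$digest, cli::hash_sha256(sig$canonical_string))
  expect_error(concept_signature(ed, "zz"), class = "taxcat_lookup_error")
})

test_that("higher taxa fall back to (name, lineage) signatures", {
  ed <- tiny_edition()
  sig <- concept_signature(ed, "g1")$canonical_string
  expect_match(sig, "^H")
  expect_match(sig, "Plantae")
  # moving the genus under a different family changes its signature
  moved <- checklist_edition(rbind(
    ed$taxa[ed$taxa$record_id != "g1", ],
    make_taxa_row("f2", "Malvaceae", "family", "k1"),
    make_taxa_row("g1", "Rosa", "genus", "f2")
  ), "ed2")
  expect_false(concept_signature(moved, "g1")$canonical_string == sig)
})

test_that("an edition matched against itself pairs everything", {
  ed <- generate_edition(8, seed = 21, edition_token = "selfa")
  copy <- ed
  copy$edition_token <- "selfb"
  m <- match_editions(ed, copy)
  expect_equal(nrow(m$pairs), n_taxa(ed))
  expect_length(m$unmatched_old, 0)
  expect_length(m$unmatched_new, 0)
  expect_identical(m$pairs$old_id, m$pairs$new_id)
})

test_that("matching is symmetric in its two arguments", {
  ed <- generate_edition(6, seed = 31)
  mut <- mutate_edition(ed, list(
    mutation_op("rename", ed$taxa$record_id[ed$taxa$rank == "species"][1]),
    mutation_op("add_taxon", payload = list(
      parent_id = ed$taxa$record_id[ed$taxa$rank == "genus"][1]))
  ), seed = 32)
  m_fwd <- match_editions(ed, mut$edition)
  m_rev <- match_editions(mut$edition, ed)
  expect_setequal(paste(m_fwd$pairs$old_id, m_fwd$pairs$new_id),
                  paste(m_rev$pairs$new_id, m_rev$pairs$old_id))
  expect_identical(m_fwd$unmatched_old, m_rev$unmatched_new)
  expect_identical(m_fwd$unmatched_new, m_rev$unmatched_old)
})

test_that("sort-adjacency matching equals the brute-force all-pairs oracle", {
  for (seed in 1:6) {
    ed <- generate_edition(10, seed = seed, edition_token = "bruta")
    sp <- ed$taxa$record_id[ed$taxa$rank == "species"]
    withr::with_seed(seed + 100, {
      ops <- list(
        mutation_op("rename", sample(sp, 1)),
        mutation_op("add_synonym", sample(setdiff(sp, ""), 1)),
        mutation_op("edit_distribution", sample(sp, 1)),
        mutation_op("remove_taxon", sample(sp, 1))
      )
      # targets must not conflict
      ops <- ops[!duplicated(vapply(ops, function(o) o$target, character(1)))]
    })
    mut <- mutate_edition(ed, ops, seed = seed + 200, new_token = "brutb")
    m <- match_editions(ed, mut$edition)
    expect_same_match(m, oracle_match(ed, mut$edition))
  }
})

test_that("duplicate signatures within an edition are flagged, never paired", {
  base <- tiny_edition()
  clone <- base$taxa[base$taxa$record_id == "s2", ]
  clone$record_id <- "s2b"
  dup <- checklist_edition(rbind(base$taxa, clone), "dup1")
  m <- match_editions(dup, base)
  expect_length(m$ambiguous_groups, 1)
  expect_setequal(m$ambiguous_groups[[1]]$old_ids, c("s2", "s2b"))
  expect_true(all(c("s2", "s2b") %in% m$unmatched_old))
  expect_true("s2" %in% m$unmatched_new)
  expect_false("s2" %in% m$pairs$old_id)
})

test_that("no false negatives: each compared field flags exactly its record", {
  ed <- generate_edition(12, seed = 41, edition_token = "nfna")
  sp <- ed$taxa$record_id[ed$taxa$rank == "species"]
  field_ops <- list(
    accepted_name = function(id) mutation_op("rename", id),
    synonyms      = function(id) mutation_op("add_synonym", id),
    vernaculars   = NULL,  # handled below (direct edit)
    distribution  = function(id) mutation_op("edit_distribution", id),
    provider_id   = function(id) mutation_op("change_provider_id", id)
  )
  withr::with_seed(42, targets <- sample(sp, 8))
  k <- 0
  for (field in c("accepted_name", "synonyms", "distribution", "provider_id")) {
    k <- k + 1
    id <- targets[k]
    mut <- mutate_edition(ed, field_ops[[field]](id), seed = 50 + k,
                          new_token = "nfnb")
    m <- match_editions(ed, mut$edition)
    expect_identical(m$unmatched_old, id)
    expect_identical(m$unmatched_new, id)
  }
  # vernacular change, edited in place
  id <- targets[5]
  mod <- ed
  i <- match(id, mod$taxa$record_id)
  mod$taxa$vernaculars[[i]] <- c(mod$taxa$vernaculars[[i]], "new common name")
  mod$taxa$vernacular_lang[[i]] <- c(mod$taxa$vernacular_lang[[i]], "en")
  m <- match_editions(ed, mod)
  expect_identical(m$unmatched_old, id)
  # lineage of a higher taxon: reparent one genus under another family
  fams <- ed$taxa$record_id[ed$taxa$rank == "family"]
  gen <- ed$taxa[ed$taxa$rank == "genus", ]
  g <- gen$record_id[1]
  other_fam <- setdiff(fams, gen$parent_id[1])[1]
  mod <- ed
  mod$taxa$parent_id[match(g, mod$taxa$record_id)] <- other_fam
  m <- match_editions(ed, mod)
  expect_identical(m$unmatched_old, g)
})

test_that("digest collisions cannot create pairs", {
  # two records engineered to share a digest but not a canonical string can
  # never arise from SHA-256 in practice; instead verify the code path:
  # pairing is decided on canonical strings, so records with equal digests
  # recorded by a corrupted index would still not pair unless strings match.
  ed <- tiny_edition()
  s <- concept_signatures(ed)
  expect_equal(anyDuplicated(s$canonical_string), 0L)
  expect_equal(anyDuplicated(s$digest), 0L)
})

test_that("assign_lsids retains UUIDs for pairs and mints for new concepts", {
  old <- generate_edition(5, seed = 61, edition_token = "lsa")
  minter <- lsid_minter(62)
  old_map <- mint_map(old, minter, version = "lsa")
  sp <- old$taxa$record_id[old$taxa$rank == "species"]
  mut <- mutate_edition(old, list(
    mutation_op("rename", sp[1]),
    mutation_op("add_taxon", payload = list(
      parent_id = old$taxa$record_id[old$taxa$rank == "genus"][1]))
  ), seed = 63, new_token = "lsb")
  m <- match_editions(old, mut$edition)
  asg <- assign_lsids(mut$edition, m, old_map, "lsb", minter)

  expect_setequal(asg$new_lsids$record_id, mut$edition$taxa$record_id)
  for (k in seq_len(nrow(m$pairs))) {
    o <- old_map[[m$pairs$old_id[k]]]
    n <- asg$new_lsids$lsid[asg$new_lsids$record_id == m$pairs$new_id[k]]
    expect_true(same_concept(o, n))
    expect_equal(parse_lsid(n)$version, "lsb")
  }
  # unmatched new records carry UUIDs unseen in the old map
  old_objects <- vapply(old_map, function(u) parse_lsid(u)$object_id, character(1))
  for (id in m$unmatched_new) {
    n <- asg$new_lsids$lsid[asg$new_lsids$record_id == id]
    expect_false(parse_lsid(n)$object_id %in% old_objects)
  }
  # deprecated = unmatched old, LSIDs retained verbatim
  expect_identical(asg$deprecated$record_id, m$unmatched_old)
  expect_identical(asg$deprecated$lsid, unname(old_map[m$unmatched_old]))
  # identity conservation both ways
  for (id in m$unmatched_old) {
    dep <- old_map[[id]]
    expect_false(any(vapply(asg$new_lsids$lsid, same_concept, logical(1), dep)))
  }

  expect_error(assign_lsids(mut$edition, m, old_map[-1], "lsb", minter),
               class = "taxcat_coverage_error")
})

test_that("an empty old edition means every record is minted fresh", {
  empty <- checklist_edition(empty_taxa_tbl(), "nil")
  new <- tiny_edition("new1")
  m <- match_editions(empty, new)
  expect_equal(length(m$unmatched_new), n_taxa(new))
  asg <- assign_lsids(new, m, character(), "new1", lsid_minter(1))
  expect_equal(anyDuplicated(asg$new_lsids$lsid), 0L)
  expect_equal(nrow(asg$deprecated), 0L)
})

test_that("synonym-addition heuristic promotes only truly novel synonyms", {
  ed <- generate_edition(8, seed = 71, edition_token = "ha")
  sp <- ed$taxa[ed$taxa$rank == "species", ]
  target <- sp$record_id[1]
  other_accepted <- sp$scientific_name[2]

  novel <- mutate_edition(ed, mutation_op(
    "add_synonym", target, payload = list(name = "Novaplanta inventa Sm.")
  ), seed = 72, new_token = "hb")
  m0 <- match_editions(ed, novel$edition)
  expect_true(target %in% m0$unmatched_old)  # strict mode: not paired

  m1 <- apply_heuristics(m0, ed, novel$edition, rules = "synonym_add")
  expect_true(any(m1$pairs$old_id == target & m1$pairs$new_id == target))
  expect_false(target %in% m1$unmatched_old)
  expect_equal(m1$promotions$rule, "synonym_add")

  # a synonym equal to another accepted name elsewhere blocks promotion
  stolen <- mutate_edition(ed, mutation_op(
    "add_synonym", target, payload = list(name = other_accepted)
  ), seed = 73, new_token = "hc")
  m2 <- apply_heuristics(match_editions(ed, stolen$edition),
                         ed, stolen$edition, rules = "synonym_add")
  expect_true(target %in% m2$unmatched_old)
  expect_equal(nrow(m2$promotions), 0L)

  expect_error(apply_heuristics(m0, ed, novel$edition, rules = "bogus"),
               class = "taxcat_parameter_error")
})

test_that("change statistics reproduce a known mutation log", {
  e1 <- generate_edition(10, seed = 81, edition_token = "ca")
  sp1 <- e1$taxa$record_id[e1$taxa$rank == "species"]
  mut12 <- mutate_edition(e1, list(
    mutation_op("rename", sp1[2]),
    mutation_op("edit_distribution", sp1[4])
  ), seed = 82, new_token = "cb")
  e2 <- mut12$edition
  sp2 <- e2$taxa$record_id[is_species_level(e2$taxa$rank)]
  mut23 <- mutate_edition(e2, list(
    mutation_op("remove_taxon", sp2[1]),
    mutation_op("add_synonym", sp2[3])
  ), seed = 83, new_token = "cc")
  e3 <- mut23$edition

  st <- change_stats(list(e1, e2, e3))
  expect_equal(st$edition_token, c("ca", "cb", "cc"))
  n_sp <- function(e) sum(is_species_level(e$taxa$rank))
  expect_equal(st$n_species_taxa, c(n_sp(e1), n_sp(e2), n_sp(e3)))

  gt12_sp <- intersect(mut12$ground_truth$expected_changed, sp1)
  expect_equal(st$lost_to_following[1], length(gt12_sp))
  expect_equal(st$shared_with_previous[2],
               length(intersect(mut12$ground_truth$expected_unchanged,
                                e1$taxa$record_id[is_species_level(e1$taxa$rank)])))
  gt23_sp <- intersect(mut23$ground_truth$expected_changed, sp2)
  expect_equal(st$lost_to_following[2], length(gt23_sp))
  expect_true(is.na(st$shared_with_previous[1]))
  expect_true(is.na(st$lost_to_following[3]))
  # pigeonhole: shared never exceeds either adjacent total
  for (i in 2:3) {
    expect_lte(st$shared_with_previous[i],
               min(st$n_species_taxa[i - 1], st$n_species_taxa[i]))
  }
  expect_error(change_stats(list(e1)), class = "taxcat_arity_error")
})

test_that("provider GUID shortcut pairs on shared GUIDs when enabled", {
  ed <- tiny_edition("pg1")
  ed$taxa$provider_taxon_guid[ed$taxa$record_id == "s1"] <- "guid-1"
  ed$taxa$provider_id[ed$taxa$record_id == "s1"] <- "prov"
  changed <- ed
  changed$edition_token <- "pg2"
  i <- match("s1", changed$taxa$record_id)
  changed$taxa$distribution[i] <- "Changed range"
  m_strict <- match_editions(ed, changed)
  expect_true("s1" %in% m_strict$unmatched_old)
  m_guid <- match_editions(ed, changed,
                           config = match_config(use_provider_guid = TRUE))
  expect_true(any(m_guid$pairs$old_id == "s1" & m_guid$pairs$new_id == "s1"))
})
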
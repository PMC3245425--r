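# Synthetic edition generation, concept mutation with ground truth, and the
# hand-encoded worked-example fixtures.

test_that("generation is deterministic and produces valid editions", {
  e1 <- generate_edition(5, species_per_genus = 4, seed = 1)
  e2 <- generate_edition(5, species_per_genus = 4, seed = 1)
  expect_identical(e1, e2)
  expect_equal(nrow(validate_edition(e1)), 0L)
  expect_false(identical(e1, generate_edition(5, species_per_genus = 4, seed = 2)))
  # names are unique within the edition (no accidental ambiguous signatures)
  expect_equal(anyDuplicated(e1$taxa$scientific_name), 0L)
  expect_equal(anyDuplicated(concept_signatures(e1)$canonical_string), 0L)
})

test_that("generator rates are honoured at their extremes", {
  none <- generate_edition(4, synonym_rate = 0, vernacular_rate = 0, seed = 3)
  expect_equal(sum(lengths(none$taxa$synonyms)), 0L)
  expect_equal(sum(lengths(none$taxa$vernaculars)), 0L)
  all_syn <- generate_edition(4, synonym_rate = 1, seed = 3)
  sp <- all_syn$taxa$rank == "species"
  expect_true(all(lengths(all_syn$taxa$synonyms[sp]) > 0))
  expect_error(generate_edition(0, seed = 1), class = "taxcat_parameter_error")
  expect_error(generate_edition(3, synonym_rate = 2, seed = 1),
               class = "taxcat_parameter_error")
})

test_that("mutation ground truth predicts the matcher outcome exactly", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      ed <- generate_edition(8, seed = 500 + rep)
      sp <- ed$taxa$record_id[ed$taxa$rank == "species"]
      picks <- sample(sp, 5)
      ops <- list(
        mutation_op("rename", picks[1]),
        mutation_op("add_synonym", picks[2]),
        mutation_op("edit_distribution", picks[3]),
        mutation_op("change_provider_id", picks[4]),
        mutation_op("remove_taxon", picks[5]),
        mutation_op("add_taxon", payload = list(
          parent_id = ed$taxa$record_id[ed$taxa$rank == "genus"][1]))
      )
      mut <- mutate_edition(ed, ops, seed = 600 + rep)
      m <- match_editions(ed, mut$edition)
      expect_identical(m$unmatched_old, mut$ground_truth$expected_changed)
      expect_identical(
        sort(intersect(m$pairs$old_id, ed$taxa$record_id), method = "radix"),
        mut$ground_truth$expected_unchanged
      )
    }
  })
})

test_that("an empty ops list changes nothing and everything pairs", {
  ed <- generate_edition(4, seed = 9)
  mut <- mutate_edition(ed, list(), seed = 10)
  expect_length(mut$ground_truth$expected_changed, 0)
  m <- match_editions(ed, mut$edition)
  expect_length(m$unmatched_old, 0)
  expect_length(m$unmatched_new, 0)
})

test_that("renaming a higher taxon changes its descendants' lineages", {
  ed <- generate_edition(6, seed = 13)
  fam <- ed$taxa$record_id[ed$taxa$rank == "family"][1]
  genera_below <- ed$taxa$record_id[ed$taxa$rank == "genus" &
                                      ed$taxa$parent_id == fam]
  mut <- mutate_edition(ed, mutation_op("rename", fam), seed = 14)
  expect_setequal(mut$ground_truth$expected_changed, c(fam, genera_below))
  m <- match_editions(ed, mut$edition)
  expect_identical(m$unmatched_old, mut$ground_truth$expected_changed)
})

test_that("lump reproduces the species-to-variety synonym swap", {
  e8 <- paper_fixture("droseraceae_2008")
  fil <- e8$taxa$record_id[e8$taxa$scientific_name == "Drosera filiformis Raf."]
  tra <- e8$taxa$record_id[e8$taxa$scientific_name == "Drosera tracyi Macfarl."]
  mut <- mutate_edition(e8, mutation_op("lump", c(fil, tra)), seed = 15,
                        new_token = "ac2009")
  t <- mut$edition$taxa
  # the absorbed species is gone; a variety of the survivor carries its name
  expect_false(tra %in% t$record_id)
  var_row <- t[t$scientific_name == "Drosera filiformis var. tracyi", ]
  expect_equal(nrow(var_row), 1L)
  expect_equal(var_row$rank, "variety")
  expect_equal(t$scientific_name[match(var_row$parent_id, t$record_id)],
               "Drosera filiformis Raf.")
  expect_equal(var_row$synonyms[[1]], "Drosera tracyi Macfarl.")
  expect_setequal(mut$ground_truth$expected_changed, tra)

  # ... matching the hand-encoded 2009 topology for that pair
  e9 <- paper_fixture("droseraceae_2009")
  v9 <- e9$taxa[e9$taxa$scientific_name == "Drosera filiformis var. tracyi", ]
  expect_equal(v9$rank, var_row$rank)
  expect_equal(v9$synonyms[[1]], var_row$synonyms[[1]])
  expect_equal(
    e9$taxa$scientific_name[match(v9$parent_id, e9$taxa$record_id)],
    "Drosera filiformis Raf."
  )
})

test_that("split elevates varieties back to species", {
  e9 <- paper_fixture("droseraceae_2009")
  fil <- e9$taxa$record_id[e9$taxa$scientific_name == "Drosera filiformis Raf."]
  var <- e9$taxa$record_id[e9$taxa$scientific_name == "Drosera filiformis var. tracyi"]
  mut <- mutate_edition(e9, mutation_op("split", fil,
                                        payload = list(children = var)),
                        seed = 16, new_token = "ac2008")
  t <- mut$edition$taxa
  expect_false(var %in% t$record_id)
  sp <- t[t$scientific_name == "Drosera tracyi Macfarl.", ]
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$rank, "species")
  expect_equal(sp$synonyms[[1]], "Drosera filiformis var. tracyi")
  expect_setequal(mut$ground_truth$expected_changed, var)
})

test_that("conflicting or invalid mutations raise typed errors", {
  ed <- generate_edition(4, seed = 17)
  sp <- ed$taxa$record_id[ed$taxa$rank == "species"][1]
  expect_error(
    mutate_edition(ed, list(mutation_op("rename", sp),
                            mutation_op("edit_distribution", sp)), seed = 1),
    class = "taxcat_conflict_error"
  )
  expect_error(mutate_edition(ed, mutation_op("rename", "nope"), seed = 1),
               class = "taxcat_lookup_error")
  expect_error(mutation_op("teleport", sp), class = "taxcat_parameter_error")
  expect_error(mutate_edition(ed, mutation_op("lump", sp), seed = 1),
               class = "taxcat_parameter_error")
})

test_that("the worked-example fixtures encode the published facts", {
  e8 <- paper_fixture("droseraceae_2008")
  e9 <- paper_fixture("droseraceae_2009")
  genus_names <- function(e) e$taxa$scientific_name[e$taxa$rank == "genus"]
  expect_true(all(c("Dionaea", "Drosera") %in% genus_names(e8)))
  expect_true(all(c("Aldrovanda", "Dionaea", "Drosera", "Drosophyllum") %in%
                    genus_names(e9)))
  # both editions place Droseraceae under Nepenthales
  for (e in list(e8, e9)) {
    fam <- e$taxa$record_id[e$taxa$scientific_name == "Droseraceae"]
    expect_equal(lineage(e, fam), "Nepenthales")
  }
  # 2008: Drosera tracyi is the species, the variety name its synonym
  tra8 <- e8$taxa[e8$taxa$scientific_name == "Drosera tracyi Macfarl.", ]
  expect_equal(tra8$rank, "species")
  expect_equal(tra8$synonyms[[1]], "Drosera filiformis var. tracyi")
  # 2009: the opposite way around
  var9 <- e9$taxa[e9$taxa$scientific_name == "Drosera filiformis var. tracyi", ]
  expect_equal(var9$rank, "variety")
  expect_equal(var9$synonyms[[1]], "Drosera tracyi Macfarl.")
  expect_error(paper_fixture("atlantis"), class = "taxcat_lookup_error")
})

test_that("the command-line dispatcher drives the core operations", {
  ed_path <- withr::local_tempfile(fileext = ".tsv")
  out_path <- withr::local_tempfile(fileext = ".tsv")
  expect_output(taxcat_main(c("synth", "--genera", "3", "--seed", "4",
                              "--out", ed_path)), "wrote")
  expect_output(taxcat_main(c("validate", ed_path)), "no violations")
  expect_output(
    taxcat_main(c("lsid", "parse",
                  "urn:lsid:catalogueoflife.org:taxon:2d99e882-0000-4000-8000-000000000001:ac2008")),
    "ac2008")
  # a full match run over two generated editions
  ed <- read_checklist(ed_path, "cli1")
  map <- mint_map(ed, lsid_minter(5), version = "cli1")
  map_path <- withr::local_tempfile(fileext = ".tsv")
  write_lsid_map(map, map_path)
  new_path <- withr::local_tempfile(fileext = ".tsv")
  mut <- mutate_edition(ed, mutation_op(
    "rename", ed$taxa$record_id[ed$taxa$rank == "species"][1]), seed = 6)
  write_checklist(mut$edition, new_path)
  report <- withr::local_tempfile(fileext = ".json")
  expect_output(
    taxcat_main(c("match", "--old", ed_path, "--new", new_path,
                  "--old-lsids", map_path, "--new-token", "cli2",
                  "--out", out_path, "--report", report)),
    "pair")
  rep <- jsonlite::read_json(report)
  expect_equal(unlist(rep$unmatched_old),
               mut$ground_truth$expected_changed)
  expect_true(file.exists(out_path))
})
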
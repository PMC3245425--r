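# Deterministic generator of synthetic checklist editions and of concept
# mutations with exact ground-truth change logs.  Names are assembled from
# syllable tables and kept unique within an edition, so no accidental
# signature duplicates can arise.

.syllables <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
                "pa", "qui", "ro", "sa", "ti", "ur", "vo", "xa", "ye", "zo",
                "bra", "cle", "dro", "fle", "gra", "pli", "stre", "tru")
.authors <- c("L.", "Lam.", "DC.", "Roxb.", "Benth.", "Hook.f.", "Mill.",
              "Willd.", "Sm.", "R.Br.")
.regions <- c("Africa", "Asia-Temperate", "Asia-Tropical", "Australasia",
              "Europe", "Northern America", "Southern America", "Pacific")
.vern_words <- c("marsh", "dwarf", "giant", "spotted", "creeping", "golden",
                 "slender", "mountain", "river", "sand")
.vern_nouns <- c("weed", "wort", "cress", "moss", "fern", "grass", "sedge",
                 "lily", "thorn", "berry")
.languages <- c("en", "fr", "de", "es", "pt")

new_name_pool <- function() {
  e <- new.env(parent = emptyenv(), hash = TRUE)
  e
}

# Draw a fresh capitalised or lower-case syllable word, unique in `pool`.
draw_word <- function(pool, capitalise = FALSE, n_syll = 2:4) {
  repeat {
    w <- paste(sample(.syllables, sample(n_syll, 1), replace = TRUE),
               collapse = "")
    if (capitalise) {
      w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }
    if (is.null(pool[[w]])) {
      pool[[w]] <- TRUE
      return(w)
    }
  }
}

draw_binomial <- function(pool, genus = NULL, with_author = TRUE) {
  g <- genus %||% draw_word(pool, capitalise = TRUE)
  n <- paste(g, draw_word(pool))
  if (with_author) paste(n, sample(.authors, 1)) else n
}

#' Generate a synthetic checklist edition
#'
#' Builds a fully valid edition with a complete kingdom-to-species hierarchy
#' (one kingdom/phylum/class, orders and families sized from the genus
#' count), plausible binomial-style names unique within the edition, and
#' randomised synonyms, vernacular names, distribution texts, provider
#' identifiers and occasional infraspecific taxa.  Fully reproducible under a
#' fixed seed.
#'
#' @param n_genera Number of genera (positive).
#' @param species_per_genus Mean number of species per genus (each genus gets
#'   `1 + Poisson(species_per_genus - 1)` species).
#' @param synonym_rate Probability that a species carries synonyms.
#' @param vernacular_rate Probability that a species carries vernacular
#'   names.
#' @param infraspecies_rate Probability that a species carries one variety.
#' @param seed Integer seed.
#' @param edition_token Edition token.
#' @return A [checklist_edition()] that passes [validate_edition()] cleanly.
#' @export
generate_edition <- function(n_genera, species_per_genus = 4,
                             synonym_rate = 0.3, vernacular_rate = 0.2,
                             infraspecies_rate = 0.1, seed,
                             edition_token = "syn1") {
  if (!is.numeric(n_genera) || n_genera < 1) {
    abort_parameter("n_genera must be a positive count")
  }
  if (species_per_genus < 1) {
    abort_parameter("species_per_genus must be at least 1")
  }
  for (p in c(synonym_rate, vernacular_rate, infraspecies_rate)) {
    if (p < 0 || p > 1) abort_parameter("rates must lie in [0, 1]")
  }
  n_genera <- as.integer(n_genera)

  withr::with_seed(as.integer(seed), {
    pool <- new_name_pool()
    rows <- list()
    idc <- 0L
    next_id <- function() {
      idc <<- idc + 1L
      sprintf("t%05d", idc)
    }
    add_row <- function(name, rank, parent, distribution = NA_character_,
                        provider = NA_character_, synonyms = character(),
                        vernaculars = character(), vlang = character()) {
      id <- next_id()
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        record_id = id, scientific_name = name, rank = rank,
        status = "accepted", parent_id = parent %||% NA_character_,
        distribution = distribution, provider_id = provider,
        provider_taxon_guid = NA_character_, provider_name_guid = NA_character_,
        citation = NA_character_,
        synonyms = list(synonyms), vernaculars = list(vernaculars),
        vernacular_lang = list(vlang)
      )
      id
    }

    kingdom <- add_row(draw_word(pool, TRUE), "kingdom", NULL)
    phylum  <- add_row(paste0(draw_word(pool, TRUE), "phyta"), "phylum", kingdom)
    klass   <- add_row(paste0(draw_word(pool, TRUE), "opsida"), "class", phylum)
    n_fam <- max(2L, ceiling(n_genera / 3))
    n_ord <- max(1L, ceiling(n_fam / 4))
    orders <- vapply(seq_len(n_ord), function(i) {
      add_row(paste0(draw_word(pool, TRUE), "ales"), "order", klass)
    }, character(1))
    families <- vapply(seq_len(n_fam), function(i) {
      add_row(paste0(draw_word(pool, TRUE), "aceae"), "family",
              orders[((i - 1L) %% n_ord) + 1L])
    }, character(1))

    prov_counter <- 0L
    for (gi in seq_len(n_genera)) {
      fam_i <- ((gi - 1L) %% n_fam) + 1L
      genus_name <- draw_word(pool, TRUE)
      genus <- add_row(genus_name, "genus", families[fam_i])
      n_sp <- 1L + stats::rpois(1, max(0, species_per_genus - 1))
      for (si in seq_len(n_sp)) {
        prov_counter <- prov_counter + 1L
        syns <- character()
        if (stats::runif(1) < synonym_rate) {
          syns <- vapply(seq_len(1L + stats::rpois(1, 0.5)),
                         function(i) draw_binomial(pool), character(1))
        }
        verns <- character(); vlang <- character()
        if (stats::runif(1) < vernacular_rate) {
          nv <- 1L + stats::rpois(1, 0.4)
          verns <- vapply(seq_len(nv), function(i) {
            paste(sample(.vern_words, 1), sample(.vern_nouns, 1))
          }, character(1))
          vlang <- sample(.languages, nv, replace = TRUE)
        }
        dist <- paste(sample(.regions, sample(1:3, 1)), collapse = "; ")
        sp_name <- draw_binomial(pool, genus = genus_name)
        sp <- add_row(sp_name, "species", genus,
                      distribution = dist,
                      provider = sprintf("gsd%02d:%05d", fam_i, prov_counter),
                      synonyms = syns, vernaculars = verns, vlang = vlang)
        if (stats::runif(1) < infraspecies_rate) {
          prov_counter <- prov_counter + 1L
          binom <- sub("\\s+[A-Z].*$", "", sp_name)  # strip authorship
          epithet <- draw_word(pool)
          add_row(paste(binom, "var.", epithet), "variety", sp,
                  distribution = dist,
                  provider = sprintf("gsd%02d:%05d", fam_i, prov_counter))
        }
      }
    }
    checklist_edition(do.call(rbind, rows), edition_token)
  })
}

# ---------------------------------------------------------------------------

.mutation_kinds <- c("rename", "lump", "split", "add_synonym",
                     "remove_synonym", "edit_distribution", "add_taxon",
                     "remove_taxon", "change_provider_id")

#' Describe one concept mutation
#'
#' @param kind One of `rename`, `lump`, `split`, `add_synonym`,
#'   `remove_synonym`, `edit_distribution`, `add_taxon`, `remove_taxon`,
#'   `change_provider_id`.
#' @param target Record id(s) the operation applies to; `lump` takes at least
#'   two species (survivor first), `add_taxon` takes none.
#' @param payload Operation-specific named list (e.g. `new_name`, `name`,
#'   `text`, `rank`, `parent_id`).
#' @return An object of class `mutation_op`.
#' @seealso [mutate_edition()]
#' @export
mutation_op <- function(kind, target = character(), payload = list()) {
  if (!kind %in% .mutation_kinds) {
    abort_parameter(paste0("Unknown mutation kind '", kind, "'"))
  }
  structure(list(kind = kind, target = as.character(target), payload = payload),
            class = "mutation_op")
}

#' Apply concept mutations to an edition, with ground truth
#'
#' Applies a list of [mutation_op()]s and returns both the mutated edition
#' and the exact expected outcome of [match_editions()] between source and
#' result: the set of source records whose concept signature was changed (or
#' which were removed), and its complement.
#'
#' `lump` follows the canonical lump pattern: the absorbed species disappear
#' and each survives as a variety of the surviving species, carrying its old
#' accepted name as a synonym.  `split` reverses it: listed varieties of the
#' target species are elevated to species in the same genus, each keeping its
#' old variety name as a synonym.
#'
#' @param edition Source [checklist_edition()].
#' @param ops List of [mutation_op()]s (a single op may be passed bare).
#' @param seed Integer seed for ops that draw random payloads (fresh names,
#'   distributions, ...).
#' @param new_token Edition token of the mutated edition; defaults to the
#'   source token suffixed with `"m"`.
#' @return A list with `edition` (the mutated [checklist_edition()]) and
#'   `ground_truth` (class `ground_truth`: `applied_ops`,
#'   `expected_changed`, `expected_unchanged`).
#' @export
mutate_edition <- function(edition, ops, seed, new_token = NULL) {
  stopifnot(inherits(edition, "checklist_edition"))
  if (inherits(ops, "mutation_op")) ops <- list(ops)
  stopifnot(all(vapply(ops, inherits, logical(1), "mutation_op")))
  new_token <- new_token %||% paste0(edition$edition_token, "m")

  targets <- unlist(lapply(ops, `[[`, "target"))
  dup <- unique(targets[duplicated(targets)])
  if (length(dup)) {
    abort_conflict(paste0("Conflicting operations on record(s): ",
                          paste(dup, collapse = ", ")))
  }
  missing_t <- setdiff(targets, edition$taxa$record_id)
  if (length(missing_t)) {
    abort_lookup(paste0("Mutation target(s) not in edition: ",
                        paste(missing_t, collapse = ", ")))
  }

  source_ids <- edition$taxa$record_id
  withr::with_seed(as.integer(seed), {
    pool <- new_name_pool()
    for (nm in c(edition$taxa$scientific_name,
                 unlist(edition$taxa$synonyms, use.names = FALSE))) {
      for (w in strsplit(nm, " ", fixed = TRUE)[[1]]) pool[[w]] <- TRUE
    }
    t <- edition$taxa
    changed <- character()
    newc <- 0L
    fresh_id <- function() {
      newc <<- newc + 1L
      sprintf("n%05d", newc)
    }
    row_of <- function(id) match(id, t$record_id)
    descendants <- function(id) {
      out <- character()
      frontier <- id
      while (length(frontier)) {
        kids <- t$record_id[!is.na(t$parent_id) & t$parent_id %in% frontier]
        out <- c(out, kids)
        frontier <- kids
      }
      out
    }

    for (op in ops) {
      k <- op$kind
      p <- op$payload
      if (k == "rename") {
        i <- row_of(op$target)
        t$scientific_name[i] <- p$new_name %||%
          (if (is_species_level(t$rank[i])) {
            draw_binomial(pool, genus = strsplit(t$scientific_name[i], " ")[[1]][1])
          } else draw_word(pool, TRUE))
        changed <- c(changed, op$target)
        if (!is_species_level(t$rank[i])) {
          # the lineage of every descendant higher taxon now reads differently
          dd <- descendants(op$target)
          hi <- dd[!is_species_level(t$rank[row_of(dd)])]
          changed <- c(changed, hi)
        }
      } else if (k == "add_synonym") {
        i <- row_of(op$target)
        t$synonyms[[i]] <- sort(c(t$synonyms[[i]],
                                  normalize_text(p$name %||% draw_binomial(pool))),
                                method = "radix")
        changed <- c(changed, op$target)
      } else if (k == "remove_synonym") {
        i <- row_of(op$target)
        if (!length(t$synonyms[[i]])) {
          abort_conflict(paste0("Record '", op$target, "' has no synonym to remove"))
        }
        victim <- p$name %||% t$synonyms[[i]][1]
        hit <- match(victim, t$synonyms[[i]])
        if (is.na(hit)) {
          abort_conflict(paste0("Record '", op$target, "' has no synonym '",
                                victim, "'"))
        }
        t$synonyms[[i]] <- t$synonyms[[i]][-hit]
        changed <- c(changed, op$target)
      } else if (k == "edit_distribution") {
        i <- row_of(op$target)
        new_dist <- p$text
        repeat {  # a drawn payload must actually differ from the old value
          if (!is.null(new_dist) &&
              !identical(new_dist, t$distribution[i])) break
          new_dist <- paste(sample(.regions, sample(1:3, 1)), collapse = "; ")
        }
        t$distribution[i] <- new_dist
        changed <- c(changed, op$target)
      } else if (k == "change_provider_id") {
        i <- row_of(op$target)
        new_prov <- p$provider_id
        repeat {
          if (!is.null(new_prov) && !identical(new_prov, t$provider_id[i])) break
          new_prov <- sprintf("gsd99:%05d", sample.int(99999L, 1))
        }
        t$provider_id[i] <- new_prov
        changed <- c(changed, op$target)
      } else if (k == "add_taxon") {
        parent <- p$parent_id
        if (is.null(parent) || !parent %in% t$record_id) {
          abort_lookup("add_taxon payload needs an existing parent_id")
        }
        rank <- p$rank %||% "species"
        nm <- p$name %||% if (rank == "species") {
          draw_binomial(pool, genus = t$scientific_name[row_of(parent)])
        } else {
          draw_word(pool, TRUE)
        }
        t <- rbind(t, tibble::tibble(
          record_id = fresh_id(), scientific_name = nm, rank = rank,
          status = "accepted", parent_id = parent,
          distribution = p$distribution %||% paste(sample(.regions, 1)),
          provider_id = p$provider_id %||% sprintf("gsd99:%05d", sample.int(99999L, 1)),
          provider_taxon_guid = NA_character_, provider_name_guid = NA_character_,
          citation = NA_character_, synonyms = list(character()),
          vernaculars = list(character()), vernacular_lang = list(character())
        ))
      } else if (k == "remove_taxon") {
        gone <- c(op$target, descendants(op$target))
        changed <- c(changed, intersect(gone, source_ids))
        t <- t[!t$record_id %in% gone, , drop = FALSE]
      } else if (k == "lump") {
        if (length(op$target) < 2L) {
          abort_parameter("lump needs a survivor and at least one absorbed species")
        }
        survivor <- op$target[1]
        absorbed <- op$target[-1]
        si <- row_of(survivor)
        if (!all(t$rank[row_of(op$target)] == "species")) {
          abort_parameter("lump operates on species records")
        }
        surv_binom <- sub("\\s+[A-Z].*$", "", t$scientific_name[si])
        for (a in absorbed) {
          ai <- row_of(a)
          abs_name <- t$scientific_name[ai]
          abs_epithet <- strsplit(sub("\\s+[A-Z].*$", "", abs_name), " ")[[1]][2]
          # children of the absorbed species move under the survivor
          t$parent_id[!is.na(t$parent_id) & t$parent_id == a] <- survivor
          t <- rbind(t, tibble::tibble(
            record_id = fresh_id(),
            scientific_name = paste(surv_binom, "var.", abs_epithet),
            rank = "variety", status = "accepted", parent_id = survivor,
            distribution = t$distribution[ai], provider_id = t$provider_id[ai],
            provider_taxon_guid = NA_character_, provider_name_guid = NA_character_,
            citation = NA_character_, synonyms = list(abs_name),
            vernaculars = list(character()), vernacular_lang = list(character())
          ))
          changed <- c(changed, a)
          t <- t[t$record_id != a, , drop = FALSE]
        }
      } else if (k == "split") {
        target <- op$target
        ti <- row_of(target)
        if (t$rank[ti] != "species") {
          abort_parameter("split operates on a species record")
        }
        kids <- p$children %||%
          t$record_id[!is.na(t$parent_id) & t$parent_id == target &
                        is_species_level(t$rank) & t$rank != "species"]
        if (!length(kids)) {
          abort_parameter("split needs at least one infraspecific child to elevate")
        }
        genus_id <- t$parent_id[ti]
        genus_name <- t$scientific_name[row_of(genus_id)]
        for (kid in kids) {
          ki <- row_of(kid)
          var_name <- t$scientific_name[ki]
          epithet <- tail(strsplit(var_name, " ", fixed = TRUE)[[1]], 1)
          new_name <- if (length(t$synonyms[[ki]])) t$synonyms[[ki]][1] else
            paste(genus_name, epithet)
          t <- rbind(t, tibble::tibble(
            record_id = fresh_id(), scientific_name = new_name,
            rank = "species", status = "accepted", parent_id = genus_id,
            distribution = t$distribution[ki], provider_id = t$provider_id[ki],
            provider_taxon_guid = NA_character_, provider_name_guid = NA_character_,
            citation = NA_character_, synonyms = list(var_name),
            vernaculars = list(character()), vernacular_lang = list(character())
          ))
          changed <- c(changed, kid)
          t <- t[t$record_id != kid, , drop = FALSE]
        }
      }
    }

    changed <- intersect(unique(changed), source_ids)
    out <- checklist_edition(t, new_token)
    list(
      edition = out,
      ground_truth = structure(
        list(
          applied_ops = ops,
          expected_changed = sort(changed, method = "radix"),
          expected_unchanged = sort(setdiff(source_ids, changed), method = "radix")
        ),
        class = "ground_truth"
      )
    )
  })
}
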
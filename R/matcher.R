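# The Taxon Matcher: pair records of two checklist editions whose concept
# signatures are identical, so that the paired concepts can keep their UUID
# (only the LSID version advances) while every detected difference forces a
# fresh identifier.  The aim is to generate no false negatives - a changed
# concept must never be silently paired - accepting false positives instead.

new_match_result <- function(pairs, unmatched_old, unmatched_new,
                             ambiguous_groups, promotions = NULL) {
  structure(
    list(
      pairs = pairs,
      unmatched_old = sort(unmatched_old, method = "radix"),
      unmatched_new = sort(unmatched_new, method = "radix"),
      ambiguous_groups = ambiguous_groups,
      promotions = promotions %||% tibble::tibble(
        old_id = character(), new_id = character(), rule = character()
      )
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " pair(s), ",
      length(x$unmatched_old), " unmatched old, ",
      length(x$unmatched_new), " unmatched new, ",
      length(x$ambiguous_groups), " ambiguous group(s)\n", sep = "")
  invisible(x)
}

#' Match two checklist editions by concept signature
#'
#' Builds the canonical concept signature of every record in both editions,
#' pools and sorts the signatures, and scans adjacent runs of the sorted list
#' for identical pairs (equivalent to, but much cheaper than, comparing each
#' new-edition taxon with every old-edition taxon).  Records pair only when
#' their canonical strings are identical; digests serve as an index, never as
#' the final equality test.
#'
#' Identical signatures duplicated within one edition are never silently
#' paired: all records of such a signature group go to the unmatched sets and
#' the group is reported in `ambiguous_groups`.
#'
#' @param old,new [checklist_edition()] objects (old and new edition).
#' @param config A [match_config()].  With `use_provider_guid = TRUE`,
#'   records carrying equal provider taxon GUIDs from the same provider are
#'   paired ahead of signature comparison.
#' @return An object of class `match_result`: `pairs` (tibble `old_id`,
#'   `new_id`), `unmatched_old`, `unmatched_new` (character vectors) and
#'   `ambiguous_groups` (list of lists with `canonical_string`, `old_ids`,
#'   `new_ids`).
#' @export
match_editions <- function(old, new, config = match_config()) {
  stopifnot(inherits(old, "checklist_edition"),
            inherits(new, "checklist_edition"))

  sig_old <- concept_signatures(old, config)
  sig_new <- concept_signatures(new, config)

  pre_pairs <- tibble::tibble(old_id = character(), new_id = character())
  if (isTRUE(config$use_provider_guid)) {
    pre_pairs <- guid_pairs(old, new)
    sig_old <- sig_old[!sig_old$record_id %in% pre_pairs$old_id, ]
    sig_new <- sig_new[!sig_new$record_id %in% pre_pairs$new_id, ]
  }

  pool <- rbind(
    data.frame(edition = rep("old", nrow(sig_old)),
               record_id = sig_old$record_id,
               canonical = sig_old$canonical_string, stringsAsFactors = FALSE),
    data.frame(edition = rep("new", nrow(sig_new)),
               record_id = sig_new$record_id,
               canonical = sig_new$canonical_string, stringsAsFactors = FALSE)
  )
  # The sort-adjacency scan: after sorting, identical signatures are adjacent.
  pool <- pool[order(pool$canonical, pool$edition, pool$record_id,
                     method = "radix"), , drop = FALSE]
  runs <- rle(pool$canonical)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L

  pairs_old <- character(); pairs_new <- character()
  ambiguous <- list()
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    o <- pool$record_id[idx][pool$edition[idx] == "old"]
    n <- pool$record_id[idx][pool$edition[idx] == "new"]
    if (length(o) == 1L && length(n) == 1L) {
      pairs_old <- c(pairs_old, o)
      pairs_new <- c(pairs_new, n)
    } else if (length(o) > 1L || length(n) > 1L) {
      ambiguous[[length(ambiguous) + 1L]] <- list(
        canonical_string = runs$values[k], old_ids = o, new_ids = n
      )
    }
  }

  pairs <- rbind(pre_pairs, tibble::tibble(old_id = pairs_old, new_id = pairs_new))
  pairs <- pairs[order(pairs$old_id, method = "radix"), , drop = FALSE]
  new_match_result(
    pairs = tibble::as_tibble(pairs),
    unmatched_old = setdiff(old$taxa$record_id, pairs$old_id),
    unmatched_new = setdiff(new$taxa$record_id, pairs$new_id),
    ambiguous_groups = ambiguous
  )
}

# Provider-GUID shortcut: unique equal taxon GUIDs from the same provider.
guid_pairs <- function(old, new) {
  key <- function(t) {
    ifelse(is.na(t$provider_taxon_guid) | is.na(t$provider_id), NA_character_,
           paste(t$provider_id, t$provider_taxon_guid, sep = "\x1f"))
  }
  ko <- key(old$taxa); kn <- key(new$taxa)
  shared <- intersect(ko[!is.na(ko)], kn[!is.na(kn)])
  # only keys unique on both sides pair; duplicated GUIDs fall back to
  # signature comparison
  shared <- shared[vapply(shared, function(k) {
    sum(ko == k, na.rm = TRUE) == 1L && sum(kn == k, na.rm = TRUE) == 1L
  }, logical(1))]
  tibble::tibble(
    old_id = old$taxa$record_id[match(shared, ko)],
    new_id = new$taxa$record_id[match(shared, kn)]
  )
}

# ---------------------------------------------------------------------------

#' Promote near-matches by explicit heuristic rules
#'
#' Strict signature matching treats any synonym-list growth as concept
#' change.  The `"synonym_add"` rule relaxes this: an old/new record pair
#' identical in every compared field except that the new record gained
#' synonyms, none of which occurred anywhere in the old edition (as an
#' accepted name or as a synonym), is probably the unchanged concept and is
#' promoted to a pair.  Rules are off unless listed in `rules`; every
#' promotion is logged in the result's `promotions` tibble.
#'
#' @param match A `match_result` from [match_editions()].
#' @param old,new The editions that produced `match`.
#' @param rules Character vector of enabled rules (`"synonym_add"`).
#' @param config The [match_config()] used for matching.
#' @return An updated `match_result`.
#' @export
apply_heuristics <- function(match, old, new, rules = character(),
                             config = match_config()) {
  stopifnot(inherits(match, "match_result"))
  if (!length(rules)) return(match)
  unknown <- setdiff(rules, "synonym_add")
  if (length(unknown)) {
    abort_parameter(paste0("Unknown heuristic rule(s): ",
                           paste(unknown, collapse = ", ")))
  }

  # signature with the synonym field blanked, to test "differs only by
  # synonyms"
  no_syn <- function(ed, ids) {
    blank <- ed
    blank$taxa$synonyms <- rep(list(character()), nrow(ed$taxa))
    all <- stats::setNames(canonical_strings(blank, config),
                           ed$taxa$record_id)
    all[ids]
  }
  co <- no_syn(old, match$unmatched_old)
  cn <- no_syn(new, match$unmatched_new)

  # every scientific name present anywhere in the old edition
  old_names <- unique(c(old$taxa$scientific_name,
                        unlist(old$taxa$synonyms, use.names = FALSE)))

  cand_old <- character(); cand_new <- character(); added <- character()
  for (o in match$unmatched_old) {
    ro <- edition_record(old, o)
    if (!is_species_level(ro$rank)) next
    hits <- names(cn)[cn == co[[o]]]
    for (n in hits) {
      rn <- edition_record(new, n)
      extra <- setdiff(rn$synonyms[[1]], ro$synonyms[[1]])
      if (!length(extra)) next                       # nothing added
      if (length(setdiff(ro$synonyms[[1]], rn$synonyms[[1]]))) next  # also lost some
      if (any(extra %in% old_names)) next            # synonym occurred elsewhere
      cand_old <- c(cand_old, o)
      cand_new <- c(cand_new, n)
      added <- c(added, paste(extra, collapse = "; "))
    }
  }
  # only unambiguous one-to-one promotions are applied
  ok <- !(cand_old %in% cand_old[duplicated(cand_old)]) &
        !(cand_new %in% cand_new[duplicated(cand_new)])
  promo <- tibble::tibble(
    old_id = cand_old[ok], new_id = cand_new[ok],
    rule = rep("synonym_add", sum(ok))
  )
  if (!nrow(promo)) return(match)

  pairs <- rbind(match$pairs, promo[, c("old_id", "new_id")])
  pairs <- pairs[order(pairs$old_id, method = "radix"), , drop = FALSE]
  new_match_result(
    pairs = tibble::as_tibble(pairs),
    unmatched_old = setdiff(match$unmatched_old, promo$old_id),
    unmatched_new = setdiff(match$unmatched_new, promo$new_id),
    ambiguous_groups = match$ambiguous_groups,
    promotions = rbind(match$promotions, promo)
  )
}

# ---------------------------------------------------------------------------

#' Assign versioned LSIDs to a new edition
#'
#' Paired records keep the UUID of their old-edition LSID with the version
#' field advanced to `new_token`; unmatched new records receive freshly
#' minted UUIDs; LSIDs of old records absent from the new edition are listed
#' as deprecated but never recycled (they stay resolvable in perpetuity).
#'
#' @param new The new [checklist_edition()].
#' @param match The `match_result` from [match_editions()] between the old
#'   edition and `new`.
#' @param old_map Named character vector mapping every old-edition record id
#'   to its LSID text (see [read_lsid_map()]).
#' @param new_token Version token of the new edition.
#' @param minter An [lsid_minter()] for fresh object ids.
#' @param authority,namespace Components used for freshly minted LSIDs.
#' @return An object of class `lsid_assignment`: `new_lsids` (tibble
#'   `record_id`, `lsid` covering every record of `new`) and `deprecated`
#'   (tibble `record_id`, `lsid` for old concepts absent from `new`).
#' @export
assign_lsids <- function(new, match, old_map, new_token, minter,
                         authority = "catalogueoflife.org",
                         namespace = "taxon") {
  stopifnot(inherits(new, "checklist_edition"),
            inherits(match, "match_result"),
            inherits(minter, "lsid_minter"))
  if (!grepl("^[a-z][a-z0-9]*$", new_token)) {
    abort_format(paste0("Invalid edition token: '", new_token, "'"))
  }
  old_ids <- c(match$pairs$old_id, match$unmatched_old)
  uncovered <- setdiff(old_ids, names(old_map))
  if (length(uncovered)) {
    abort_coverage(paste0("old_map does not cover old record(s): ",
                          paste(head(uncovered, 10), collapse = ", ")))
  }

  known_objects <- vapply(old_map[old_ids], function(u) parse_lsid(u)$object_id,
                          character(1))

  new_ids <- new$taxa$record_id
  out <- character(length(new_ids))
  names(out) <- new_ids
  # retained UUIDs, version advanced
  for (k in seq_len(nrow(match$pairs))) {
    o <- parse_lsid(old_map[[match$pairs$old_id[k]]])
    out[[match$pairs$new_id[k]]] <- compose_lsid(
      lsid(o$object_id, version = new_token,
           authority = o$authority, namespace = o$namespace)
    )
  }
  # fresh mints for genuinely new concepts
  for (id in match$unmatched_new) {
    u <- mint_object_id(minter, avoid = known_objects)
    out[[id]] <- compose_lsid(
      lsid(u, version = new_token, authority = authority, namespace = namespace)
    )
  }
  structure(
    list(
      new_lsids = tibble::tibble(record_id = new_ids, lsid = unname(out)),
      deprecated = tibble::tibble(
        record_id = match$unmatched_old,
        lsid = unname(old_map[match$unmatched_old])
      )
    ),
    class = "lsid_assignment"
  )
}

#' @export
print.lsid_assignment <- function(x, ...) {
  cat("<lsid_assignment> ", nrow(x$new_lsids), " LSID(s) assigned, ",
      nrow(x$deprecated), " deprecated\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Growth and change statistics across a series of editions
#'
#' For each edition of an ordered series, counts taxa at species and
#' infraspecies level, how many of them were also present (as unchanged
#' concepts) in the previous edition, and how many are not carried into the
#' following edition.  Counts derive from [match_editions()] on consecutive
#' edition pairs.
#'
#' @param editions Ordered list (oldest first) of at least two
#'   [checklist_edition()] objects.
#' @param config A [match_config()].
#' @return A tibble with columns `edition_token`, `n_species_taxa`,
#'   `shared_with_previous` (`NA` for the first edition) and
#'   `lost_to_following` (`NA` for the last edition).
#' @export
change_stats <- function(editions, config = match_config()) {
  if (length(editions) < 2L) {
    abort_arity("change_stats needs at least two editions")
  }
  stopifnot(all(vapply(editions, inherits, logical(1), "checklist_edition")))
  n <- length(editions)
  species_ids <- lapply(editions, function(e) {
    e$taxa$record_id[is_species_level(e$taxa$rank)]
  })
  shared <- rep(NA_integer_, n)
  lost <- rep(NA_integer_, n)
  for (i in seq_len(n - 1L)) {
    m <- match_editions(editions[[i]], editions[[i + 1L]], config)
    sp_pairs <- m$pairs$new_id %in% species_ids[[i + 1L]]
    shared[i + 1L] <- sum(sp_pairs)
    lost[i] <- sum(m$unmatched_old %in% species_ids[[i]])
  }
  tibble::tibble(
    edition_token = vapply(editions, function(e) e$edition_token, character(1)),
    n_species_taxa = lengths(species_ids),
    shared_with_previous = shared,
    lost_to_following = lost
  )
}
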
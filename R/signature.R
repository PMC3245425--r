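# Concept signatures.  For every taxon a single concatenated canonical string
# (and its SHA-256 digest) encodes exactly the fields whose change counts as
# evidence of concept change:
#
#   species rank and below: accepted scientific name, all synonyms, all
#   vernacular names, geographical distribution text, and the identifier
#   given by the data provider;
#   above species rank (where those fields are largely absent): accepted name
#   plus the names of the higher taxa above it.
#
# The encoding is injective over field tuples: fields are joined with the
# unit separator U+001F and values inside multi-value fields with the record
# separator U+001E, with absent fields kept as empty strings in position, so
# no two distinct field tuples can collide as strings.  Matching on such
# signatures yields no false negatives: any change in a compared field
# changes the canonical string.

.FS <- "\x1f"  # field separator
.VS <- "\x1e"  # value separator within multi-value fields

#' Matching configuration
#'
#' @param include_vernacular_language Include the language code of each
#'   vernacular name in the signature.  Off by default: the language tag is
#'   stored but a change of tag alone is not treated as concept change.
#' @param use_provider_guid When both records of a candidate pair carry a
#'   provider-assigned taxon GUID from the same provider, pair them on GUID
#'   equality ahead of signature comparison.  Off by default.
#' @param heuristics Character vector of enabled post-match heuristics for
#'   [apply_heuristics()]; currently `"synonym_add"` is understood.  Empty by
#'   default (strict no-false-negative mode).
#' @return A list of class `match_config`.
#' @export
match_config <- function(include_vernacular_language = FALSE,
                         use_provider_guid = FALSE,
                         heuristics = character()) {
  structure(
    list(include_vernacular_language = include_vernacular_language,
         use_provider_guid = use_provider_guid,
         heuristics = heuristics),
    class = "match_config"
  )
}

# Canonical strings for every record of an edition (vectorised core).
canonical_strings <- function(edition, config = match_config()) {
  t <- edition$taxa
  sp <- is_species_level(t$rank)
  out <- character(nrow(t))

  # multi-value fields are sorted and de-duplicated here (not only at
  # construction time) so that input order can never signal concept change
  vern_field <- function(i) {
    v <- t$vernaculars[[i]]
    if (config$include_vernacular_language) {
      l <- t$vernacular_lang[[i]]
      v <- paste0(v, "@", ifelse(is.na(l), "", l))
    }
    paste(sort(unique(v), method = "radix"), collapse = .VS)
  }
  na_empty <- function(x) ifelse(is.na(x), "", x)

  for (i in which(sp)) {
    out[i] <- paste(
      "S", t$scientific_name[i],
      paste(sort(unique(t$synonyms[[i]]), method = "radix"), collapse = .VS),
      vern_field(i),
      na_empty(t$distribution[i]),
      na_empty(t$provider_id[i]),
      sep = .FS
    )
  }
  if (any(!sp)) {
    for (i in which(!sp)) {
      out[i] <- paste(
        "H", t$scientific_name[i],
        paste(lineage(edition, t$record_id[i]), collapse = .VS),
        sep = .FS
      )
    }
  }
  out
}

#' Concept signature of one taxon record
#'
#' @param edition A [checklist_edition()].
#' @param record_id Record identifier.
#' @param config A [match_config()].
#' @return A list of class `taxon_signature` with `record_id`,
#'   `canonical_string` and the SHA-256 `digest` of the canonical string.
#' @seealso [concept_signatures()] for all records at once, [match_editions()]
#' @export
concept_signature <- function(edition, record_id, config = match_config()) {
  stopifnot(inherits(edition, "checklist_edition"))
  if (!record_id %in% edition$taxa$record_id) {
    abort_lookup(paste0("Unknown record_id '", record_id, "'"))
  }
  tbl <- concept_signatures(edition, config)
  i <- match(record_id, tbl$record_id)
  structure(
    list(record_id = record_id,
         canonical_string = tbl$canonical_string[i],
         digest = tbl$digest[i]),
    class = "taxon_signature"
  )
}

#' Concept signatures for every record of an edition
#'
#' @inheritParams concept_signature
#' @return A tibble with columns `record_id`, `canonical_string`, `digest`.
#' @export
concept_signatures <- function(edition, config = match_config()) {
  stopifnot(inherits(edition, "checklist_edition"))
  canon <- canonical_strings(edition, config)
  tibble::tibble(
    record_id = edition$taxa$record_id,
    canonical_string = canon,
    digest = vapply(canon, cli::hash_sha256, character(1), USE.NAMES = FALSE)
  )
}
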
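# Rank handling.  Ranks form a fixed total order; comparisons between parent
# and child records and the species-level boundary of the concept signature
# both rest on this order.  Unknown rank strings are rejected, never guessed.

# Canonical ranks, highest first.  The infraspecific ranks (variety,
# subspecies, form) share one level below species.
.rank_table <- c(
  kingdom    = 1L,
  phylum     = 2L,
  class      = 3L,
  order      = 4L,
  superfamily = 5L,
  family     = 6L,
  subfamily  = 7L,
  tribe      = 8L,
  genus      = 9L,
  subgenus   = 10L,
  species    = 11L,
  infraspecies = 12L,
  subspecies = 12L,
  variety    = 12L,
  form       = 12L
)

#' Ranks recognised by taxcat
#'
#' The closed set of taxonomic rank names accepted in checklist files, from
#' kingdom down to the infraspecific ranks (subspecies, variety, form), which
#' share a single level below species.
#'
#' @return Character vector of accepted rank names.
#' @export
taxon_ranks <- function() names(.rank_table)

normalize_rank <- function(rank, where = NULL) {
  r <- tolower(trimws(rank))
  r[r == "var."] <- "variety"
  r[r == "subsp." | r == "ssp."] <- "subspecies"
  bad <- !is.na(r) & !(r %in% names(.rank_table))
  if (any(bad)) {
    abort_format(paste0(
      "Unknown taxonRank value(s): ",
      paste(unique(r[bad]), collapse = ", "),
      if (!is.null(where)) paste0(" (rows ", paste(where[bad], collapse = ", "), ")")
    ))
  }
  r
}

# Integer level for rank comparison; larger = lower in the hierarchy.
rank_level <- function(rank) unname(.rank_table[rank])

# Species-level taxa (species and below) carry the five-field concept
# signature; taxa above species fall back to (name, lineage).
is_species_level <- function(rank) rank_level(rank) >= .rank_table[["species"]]
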
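# Checklist editions: the domain container plus a reader/validator for the
# delimited Darwin-Core-style checklist table.

# Whitespace/Unicode normalization applied to every name-like string before it
# is stored or compared: NFC form, internal whitespace collapsed to single
# spaces, leading/trailing space stripped.  Case is preserved (it carries
# nomenclatural meaning).
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

empty_taxa_tbl <- function() {
  tibble::tibble(
    record_id = character(), scientific_name = character(),
    rank = character(), status = character(), parent_id = character(),
    distribution = character(), provider_id = character(),
    provider_taxon_guid = character(), provider_name_guid = character(),
    citation = character(),
    synonyms = list(), vernaculars = list(), vernacular_lang = list()
  )
}

#' Construct a checklist edition
#'
#' A checklist edition is one released snapshot of a taxonomic catalogue: a
#' set of accepted taxon records with their names, synonyms, vernacular
#' names, distribution text and provider identifiers, arranged in a parent
#' pointer hierarchy, under an edition token such as `"ac2008"`.
#'
#' @param taxa A tibble with one row per accepted taxon.  Required columns:
#'   `record_id`, `scientific_name`, `rank`, `status`, `parent_id` (`NA` for
#'   roots).  Optional columns (`NA`/empty when absent): `distribution`,
#'   `provider_id`, `provider_taxon_guid`, `provider_name_guid`, `citation`,
#'   and list columns `synonyms`, `vernaculars`, `vernacular_lang`.
#' @param edition_token Lower-case token naming the edition, matching
#'   `[a-z][a-z0-9]*` (e.g. `"ac2009"`, `"dc"`).
#' @param check If `TRUE` (default) structural invariants are verified with
#'   [validate_edition()] and any violation raises an error.
#'
#' @return An object of class `checklist_edition`.
#' @seealso [read_checklist()], [validate_edition()], [lineage()]
#' @export
checklist_edition <- function(taxa, edition_token, check = TRUE) {
  if (!grepl("^[a-z][a-z0-9]*$", edition_token)) {
    abort_format(paste0("Invalid edition token: '", edition_token,
                        "' (must match [a-z][a-z0-9]*)"))
  }
  taxa <- as_tibble(taxa)
  required <- c("record_id", "scientific_name", "rank", "status", "parent_id")
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols)) {
    abort_format(paste0("taxa is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(taxa)
  for (col in c("distribution", "provider_id", "provider_taxon_guid",
                "provider_name_guid", "citation")) {
    if (is.null(taxa[[col]])) taxa[[col]] <- rep(NA_character_, n)
  }
  for (col in c("synonyms", "vernaculars", "vernacular_lang")) {
    if (is.null(taxa[[col]])) taxa[[col]] <- rep(list(character()), n)
  }
  taxa$record_id <- as.character(taxa$record_id)
  taxa$scientific_name <- normalize_text(taxa$scientific_name)
  taxa$rank <- normalize_rank(taxa$rank)
  taxa$status <- as.character(taxa$status)
  taxa$parent_id <- as.character(taxa$parent_id)
  # Multisets are stored sorted (C locale) so row order in the source file can
  # never influence the edition or downstream signatures.
  taxa$synonyms <- lapply(taxa$synonyms, function(s) {
    sort(normalize_text(as.character(s)), method = "radix")
  })
  vord <- lapply(taxa$vernaculars, function(v) {
    order(normalize_text(as.character(v)), method = "radix")
  })
  taxa$vernaculars <- mapply(function(v, o) normalize_text(as.character(v))[o],
                             taxa$vernaculars, vord, SIMPLIFY = FALSE)
  taxa$vernacular_lang <- mapply(function(l, v, o) {
    l <- as.character(l)
    length(l) <- length(v)  # pad with NA if languages were not given
    l[o]
  }, taxa$vernacular_lang, taxa$vernaculars, vord, SIMPLIFY = FALSE)
  taxa <- taxa[order(taxa$record_id, method = "radix"), , drop = FALSE]

  if (any(!nzchar(taxa$scientific_name))) {
    abort_format("Empty scientific name after whitespace normalization")
  }
  ed <- structure(
    list(edition_token = edition_token, taxa = taxa),
    class = "checklist_edition"
  )
  if (check) {
    rep <- validate_edition(ed)
    if (nrow(rep)) {
      thrower <- if (all(rep$issue == "orphan_parent")) abort_referential
                 else if (all(rep$issue == "duplicate_record_id")) abort_uniqueness
                 else abort_format
      thrower(paste0(
        "Edition '", edition_token, "' violates checklist invariants:\n",
        paste0("  - [", rep$issue, "] ", rep$message, collapse = "\n")
      ))
    }
  }
  ed
}

#' @export
print.checklist_edition <- function(x, ...) {
  sp <- sum(is_species_level(x$taxa$rank))
  cat("<checklist_edition> ", x$edition_token, ": ", nrow(x$taxa),
      " taxa (", sp, " at species level or below), ",
      sum(is.na(x$taxa$parent_id)), " root(s)\n", sep = "")
  invisible(x)
}

#' Number of taxon records in an edition
#'
#' @param edition A [checklist_edition()].
#' @param species_level If `TRUE`, count only taxa at species rank and below.
#' @return Integer count.
#' @export
n_taxa <- function(edition, species_level = FALSE) {
  stopifnot(inherits(edition, "checklist_edition"))
  if (species_level) sum(is_species_level(edition$taxa$rank)) else nrow(edition$taxa)
}

#' Root record identifiers of an edition
#'
#' @param edition A [checklist_edition()].
#' @return Character vector of record ids with no parent.
#' @export
root_ids <- function(edition) {
  edition$taxa$record_id[is.na(edition$taxa$parent_id)]
}

# One record as a named list (internal row accessor).
edition_record <- function(edition, record_id) {
  i <- match(record_id, edition$taxa$record_id)
  if (is.na(i)) {
    abort_lookup(paste0("Unknown record_id '", record_id, "' in edition '",
                        edition$edition_token, "'"))
  }
  as.list(edition$taxa[i, ])
}

# ---------------------------------------------------------------------------
# Reader / writer for the delimited checklist format.

.checklist_columns <- c(
  record_id  = "taxonID",
  scientific_name = "scientificName",
  rank       = "taxonRank",
  status     = "taxonomicStatus",
  parent_id  = "parentNameUsageID",
  accepted_id = "acceptedNameUsageID",
  vernacular = "vernacularName",
  language   = "language",
  distribution = "distribution",
  provider_id = "datasetID",
  provider_taxon_guid = "taxonConceptID",
  provider_name_guid  = "scientificNameID",
  citation   = "namePublishedIn"
)

#' Read a checklist edition from a delimited table
#'
#' Reads a UTF-8 delimited file (tab by default) with Darwin-Core-style
#' column names and folds synonym and vernacular rows into the accepted
#' record they point to via `acceptedNameUsageID`.  The result is independent
#' of row order.
#'
#' Rows are interpreted by `taxonomicStatus`: `accepted` and
#' `provisionally accepted` rows become taxon records; `synonym` rows
#' contribute their `scientificName` to the accepted record's synonym
#' multiset; `vernacular` (or `common name`) rows contribute their
#' `vernacularName` (falling back to `scientificName`) and `language`.
#'
#' @param path Path to the file.
#' @param edition_token Edition token (e.g. `"ac2008"`); see
#'   [checklist_edition()].
#' @param delim Field delimiter; tab by default.
#' @param col_map Named character vector overriding the default Darwin-Core
#'   column names.  Names are taxcat's internal roles (e.g. `record_id`),
#'   values are the column headers in the file.
#' @param check Passed to [checklist_edition()].
#'
#' @return A [checklist_edition()].
#' @export
read_checklist <- function(path, edition_token, delim = "\t", col_map = NULL,
                           check = TRUE) {
  if (!file.exists(path)) abort_format(paste0("File not found: ", path))
  cols <- .checklist_columns
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  raw <- read.delim(path, sep = delim, quote = "", colClasses = "character",
                    check.names = FALSE, na.strings = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  required <- cols[c("record_id", "scientific_name", "rank", "status")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort_format(paste0("Checklist file is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  get_col <- function(role) {
    if (cols[[role]] %in% names(raw)) raw[[cols[[role]]]] else rep(NA_character_, nrow(raw))
  }
  id       <- get_col("record_id")
  name     <- get_col("scientific_name")
  rank     <- get_col("rank")
  status   <- tolower(trimws(get_col("status")))
  status[status == "provisionally_accepted"] <- "provisionally accepted"
  status[status == "common name"] <- "vernacular"
  parent   <- get_col("parent_id")
  accepted <- get_col("accepted_id")
  vern     <- get_col("vernacular")
  lang     <- get_col("language")

  if (any(is.na(id))) {
    abort_format("Every row needs a taxonID (including synonym/vernacular rows)")
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    abort_uniqueness(paste0("Duplicate record id(s) in checklist file: ",
                            paste(unique(dup), collapse = ", ")))
  }
  ok_status <- c("accepted", "provisionally accepted", "synonym", "vernacular")
  if (any(!status %in% ok_status)) {
    abort_format(paste0("Unknown taxonomicStatus value(s): ",
                        paste(unique(status[!status %in% ok_status]), collapse = ", ")))
  }

  is_acc <- status %in% c("accepted", "provisionally accepted")
  acc_ids <- id[is_acc]
  ref_rows <- !is_acc
  bad_ref <- ref_rows & (is.na(accepted) | !(accepted %in% acc_ids))
  if (any(bad_ref)) {
    abort_referential(paste0(
      "Synonym/vernacular row(s) reference a missing accepted record: row id(s) ",
      paste(id[bad_ref], collapse = ", ")
    ))
  }

  taxa <- tibble::tibble(
    record_id = id[is_acc],
    scientific_name = name[is_acc],
    rank = normalize_rank(rank[is_acc], where = id[is_acc]),
    status = status[is_acc],
    parent_id = parent[is_acc],
    distribution = get_col("distribution")[is_acc],
    provider_id = get_col("provider_id")[is_acc],
    provider_taxon_guid = get_col("provider_taxon_guid")[is_acc],
    provider_name_guid = get_col("provider_name_guid")[is_acc],
    citation = get_col("citation")[is_acc]
  )
  syn_by  <- split(name[status == "synonym"], accepted[status == "synonym"])
  vn      <- ifelse(is.na(vern[status == "vernacular"]),
                    name[status == "vernacular"], vern[status == "vernacular"])
  vern_by <- split(vn, accepted[status == "vernacular"])
  lang_by <- split(lang[status == "vernacular"], accepted[status == "vernacular"])
  taxa$synonyms    <- lapply(taxa$record_id, function(i) syn_by[[i]] %||% character())
  taxa$vernaculars <- lapply(taxa$record_id, function(i) vern_by[[i]] %||% character())
  taxa$vernacular_lang <- lapply(taxa$record_id, function(i) lang_by[[i]] %||% character())

  checklist_edition(taxa, edition_token, check = check)
}

#' Write a checklist edition to a delimited table
#'
#' Inverse of [read_checklist()]: accepted records become `accepted` rows and
#' each synonym/vernacular becomes its own row pointing back via
#' `acceptedNameUsageID`.
#'
#' @param edition A [checklist_edition()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(edition, path, delim = "\t") {
  stopifnot(inherits(edition, "checklist_edition"))
  t <- edition$taxa
  acc <- data.frame(
    taxonID = t$record_id, scientificName = t$scientific_name,
    taxonRank = t$rank, taxonomicStatus = t$status,
    parentNameUsageID = t$parent_id, acceptedNameUsageID = NA_character_,
    vernacularName = NA_character_, language = NA_character_,
    distribution = t$distribution, datasetID = t$provider_id,
    taxonConceptID = t$provider_taxon_guid, scientificNameID = t$provider_name_guid,
    namePublishedIn = t$citation, stringsAsFactors = FALSE
  )
  extra <- list()
  k <- 0L
  for (i in seq_len(nrow(t))) {
    for (s in t$synonyms[[i]]) {
      k <- k + 1L
      extra[[length(extra) + 1L]] <- data.frame(
        taxonID = sprintf("%s-s%d", t$record_id[i], k), scientificName = s,
        taxonRank = t$rank[i], taxonomicStatus = "synonym",
        parentNameUsageID = NA_character_, acceptedNameUsageID = t$record_id[i],
        vernacularName = NA_character_, language = NA_character_,
        distribution = NA_character_, datasetID = NA_character_,
        taxonConceptID = NA_character_, scientificNameID = NA_character_,
        namePublishedIn = NA_character_, stringsAsFactors = FALSE
      )
    }
    for (j in seq_along(t$vernaculars[[i]])) {
      k <- k + 1L
      extra[[length(extra) + 1L]] <- data.frame(
        taxonID = sprintf("%s-v%d", t$record_id[i], k),
        scientificName = t$vernaculars[[i]][j],
        taxonRank = t$rank[i], taxonomicStatus = "vernacular",
        parentNameUsageID = NA_character_, acceptedNameUsageID = t$record_id[i],
        vernacularName = t$vernaculars[[i]][j],
        language = t$vernacular_lang[[i]][j],
        distribution = NA_character_, datasetID = NA_character_,
        taxonConceptID = NA_character_, scientificNameID = NA_character_,
        namePublishedIn = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, c(list(acc), extra))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = delim, quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Validate the structural invariants of a checklist edition
#'
#' Reports (never throws) violations of the edition invariants: duplicate
#' record ids, parent pointers to absent records, parent cycles, rank
#' inversions (a child whose rank is not strictly lower than its parent's),
#' and accepted names duplicated in their own synonym or vernacular multiset.
#'
#' @param edition A `checklist_edition` (or a bare list with a `taxa` tibble,
#'   so that unchecked candidates can be validated).
#' @return A tibble with columns `record_id`, `issue`, `message`; zero rows
#'   iff the edition is well formed.
#' @export
validate_edition <- function(edition) {
  t <- edition$taxa
  issues <- list()
  note <- function(record_id, issue, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      record_id = record_id, issue = issue, message = message
    )
  }

  dup <- unique(t$record_id[duplicated(t$record_id)])
  for (d in dup) note(d, "duplicate_record_id",
                      paste0("record_id '", d, "' occurs more than once"))

  known <- t$record_id
  orphan <- !is.na(t$parent_id) & !(t$parent_id %in% known)
  for (i in which(orphan)) {
    note(t$record_id[i], "orphan_parent",
         paste0("parent_id '", t$parent_id[i], "' does not exist"))
  }

  # Cycle detection over parent pointers (orphan pointers treated as ends).
  parent_of <- stats::setNames(t$parent_id, t$record_id)
  state <- stats::setNames(integer(length(known)), known)  # 0 new, 1 active, 2 done
  for (start in known) {
    if (state[[start]] != 0L) next
    path <- character()
    node <- start
    while (!is.na(node) && node %in% known && state[[node]] == 0L) {
      state[[node]] <- 1L
      path <- c(path, node)
      node <- parent_of[[node]]
    }
    if (!is.na(node) && node %in% known && state[[node]] == 1L) {
      cyc <- path[seq(match(node, path), length(path))]
      for (r in cyc) note(r, "cycle",
                          paste0("record '", r, "' lies on a parent-pointer cycle"))
    }
    state[path] <- 2L
  }

  lv <- rank_level(t$rank)
  pidx <- match(t$parent_id, known)
  inv <- !is.na(pidx) & !(lv > lv[pidx])
  for (i in which(inv)) {
    note(t$record_id[i], "rank_inversion",
         paste0("rank '", t$rank[i], "' of '", t$record_id[i],
                "' is not below parent rank '", t$rank[pidx[i]], "'"))
  }

  for (i in seq_len(nrow(t))) {
    if (t$scientific_name[i] %in% t$synonyms[[i]]) {
      note(t$record_id[i], "accepted_in_synonyms",
           "accepted name also listed as a synonym of itself")
    }
    if (t$scientific_name[i] %in% t$vernaculars[[i]]) {
      note(t$record_id[i], "accepted_in_vernaculars",
           "accepted name also listed as a vernacular name of itself")
    }
  }

  if (length(issues)) do.call(rbind, issues) else
    tibble::tibble(record_id = character(), issue = character(),
                   message = character())
}

#' Higher-taxon lineage of a record
#'
#' Accepted names of the ancestors of a record, ordered from the root down to
#' (and excluding) the record itself.  These are the names the concept
#' signature of a higher taxon is built from.
#'
#' @param edition A [checklist_edition()].
#' @param record_id Record identifier.
#' @return Character vector of accepted names (empty for a root).
#' @export
lineage <- function(edition, record_id) {
  stopifnot(inherits(edition, "checklist_edition"))
  t <- edition$taxa
  i <- match(record_id, t$record_id)
  if (is.na(i)) {
    abort_lookup(paste0("Unknown record_id '", record_id, "'"))
  }
  out <- character()
  seen <- character()
  p <- t$parent_id[i]
  while (!is.na(p)) {
    if (p %in% seen) abort_lookup(paste0("Parent cycle at record '", p, "'"))
    seen <- c(seen, p)
    j <- match(p, t$record_id)
    if (is.na(j)) abort_lookup(paste0("Orphan parent pointer '", p, "'"))
    out <- c(t$scientific_name[j], out)
    p <- t$parent_id[j]
  }
  out
}
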
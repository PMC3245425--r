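# Repository of typed relationships between taxon-concept LSIDs (and
# name-bearing anonymous concepts), with set-semantics inference over
# congruence and inclusion.

.relationship_types <- c(
  "HasSynonym", "HasVernacular",
  "IsParentTaxonOf", "IsChildTaxonOf",
  "IsCongruentTo", "Includes", "IsIncludedIn", "Overlaps"
)

# Declared inverses; symmetric types invert to themselves; name relations
# have no inverse.
.rel_inverse <- c(
  IsParentTaxonOf = "IsChildTaxonOf", IsChildTaxonOf = "IsParentTaxonOf",
  Includes = "IsIncludedIn", IsIncludedIn = "Includes",
  IsCongruentTo = "IsCongruentTo", Overlaps = "Overlaps"
)

# Concept-to-concept ("set") relations, for which subject == object is
# rejected; HasSynonym/HasVernacular relate a concept to a name-bearing node
# and never participate in set inference.
.set_relations <- c("IsParentTaxonOf", "IsChildTaxonOf", "IsCongruentTo",
                    "Includes", "IsIncludedIn", "Overlaps")

#' Relationship types of the concept repository
#'
#' The closed set of relationship categories: name relations (`HasSynonym`,
#' `HasVernacular`), hierarchy relations (`IsParentTaxonOf`,
#' `IsChildTaxonOf`) and concept set relations (`IsCongruentTo`, `Includes`,
#' `IsIncludedIn`, `Overlaps`).
#'
#' @return Character vector.
#' @export
relationship_types <- function() .relationship_types

empty_relations_tbl <- function() {
  tibble::tibble(subject = character(), type = character(),
                 object = character(), object_kind = character(),
                 provenance = character())
}

#' Create an empty LSID repository
#'
#' The repository stores typed, directed relationship assertions between
#' concept identifiers.  Declared inverse pairs need not be stored twice:
#' storing one direction makes the other derivable on query.
#'
#' @return An object of class `lsid_repository`.
#' @seealso [add_relation()], [query_relations()],
#'   [propagate_applicability()], [congruence_classes()]
#' @export
lsid_repository <- function() {
  structure(list(relations = empty_relations_tbl()), class = "lsid_repository")
}

#' @export
print.lsid_repository <- function(x, ...) {
  cat("<lsid_repository> ", nrow(x$relations), " stored relation(s)\n", sep = "")
  invisible(x)
}

as_id_text <- function(x) {
  if (inherits(x, "lsid")) compose_lsid(x) else as.character(x)
}

#' Add a relationship assertion to a repository
#'
#' Adding is idempotent: an assertion that is already stored, or already
#' derivable as the declared inverse of a stored assertion with the same
#' provenance, leaves the repository unchanged.  Self-referential set
#' relations (e.g. `IsCongruentTo(A, A)`) are rejected.
#'
#' @param repo An [lsid_repository()].
#' @param subject Subject LSID (object of class `lsid` or URN text).
#' @param type One of [relationship_types()].
#' @param object Object LSID, or for `object_kind = "name_guid"` a
#'   provider-assigned name GUID wrapped in an anonymous concept.
#' @param provenance Optional edition token or provider name.
#' @param object_kind `"lsid"` (default) or `"name_guid"`.
#' @return The updated repository.
#' @export
add_relation <- function(repo, subject, type, object, provenance = NA_character_,
                         object_kind = c("lsid", "name_guid")) {
  stopifnot(inherits(repo, "lsid_repository"))
  object_kind <- match.arg(object_kind)
  if (!type %in% .relationship_types) {
    abort_parameter(paste0("Unknown relationship type '", type, "'"))
  }
  subject <- as_id_text(subject)
  object <- as_id_text(object)
  if (!nzchar(subject) || !nzchar(object)) {
    abort_parameter("Relation endpoints must be non-empty")
  }
  if (type %in% .set_relations && object_kind == "lsid" && subject == object) {
    abort_parameter(paste0("Self-referential ", type, " relation rejected: ",
                           subject))
  }
  r <- repo$relations
  already <- function(s, ty, o) {
    any(r$subject == s & r$type == ty & r$object == o &
          r$object_kind == object_kind &
          (is.na(provenance) & is.na(r$provenance) |
             !is.na(provenance) & !is.na(r$provenance) & r$provenance == provenance))
  }
  inv <- if (type %in% names(.rel_inverse)) .rel_inverse[[type]] else NA_character_
  if (already(subject, type, object) ||
      (!is.na(inv) && object_kind == "lsid" && already(object, inv, subject))) {
    return(repo)
  }
  repo$relations <- rbind(r, tibble::tibble(
    subject = subject, type = type, object = object,
    object_kind = object_kind, provenance = provenance
  ))
  repo
}

# Stored relations plus derived inverses, all expressed with `about` as
# subject.
relations_about <- function(repo, about) {
  r <- repo$relations
  direct <- r[r$subject == about, , drop = FALSE]
  inc <- r[r$object == about & r$object_kind == "lsid" &
             r$type %in% names(.rel_inverse), , drop = FALSE]
  derived <- tibble::tibble(
    subject = inc$object, type = unname(.rel_inverse[inc$type]),
    object = inc$subject, object_kind = inc$object_kind,
    provenance = inc$provenance
  )
  out <- rbind(cbind(direct, derived = rep(FALSE, nrow(direct))),
               cbind(derived, derived = rep(TRUE, nrow(derived))))
  # a derived row duplicating a stored row is dropped
  key <- paste(out$subject, out$type, out$object, out$object_kind, sep = "\x1f")
  tibble::as_tibble(out[!duplicated(key), , drop = FALSE])
}

# Every identifier text in the repository that denotes the same concept as
# `l` (same authority/namespace/UUID, any version), plus `l`'s own urn.
# Relations may have been asserted against any edition's version of an LSID.
repo_aliases <- function(repo, l) {
  l <- parse_lsid(l)
  r <- repo$relations
  ids <- unique(c(r$subject, r$object[r$object_kind == "lsid"]))
  hit <- vapply(ids, function(x) {
    p <- tryCatch(parse_lsid(x), error = function(e) NULL)
    !is.null(p) && same_concept(p, l)
  }, logical(1))
  unique(c(compose_lsid(l), ids[hit]))
}

#' Query relationships about one concept
#'
#' Returns stored assertions whose subject is `about`, together with the
#' derivable inverses of stored assertions that point at `about` (e.g. a
#' stored `IsParentTaxonOf(G, S)` yields `IsChildTaxonOf(S, G)` when
#' querying `S`).
#'
#' @param repo An [lsid_repository()].
#' @param about LSID (or URN text) to query.
#' @return A tibble of relations with a logical `derived` column.
#' @export
query_relations <- function(repo, about) {
  stopifnot(inherits(repo, "lsid_repository"))
  relations_about(repo, as_id_text(about))
}

#' Derive hierarchy relations from a checklist edition
#'
#' Emits one `IsParentTaxonOf` assertion per parent-child edge of the
#' edition, with the edition token as provenance.
#'
#' @param edition A [checklist_edition()].
#' @param lsid_map Named character vector covering every record id of the
#'   edition (see [read_lsid_map()]).
#' @return A tibble of relations (`subject`, `type`, `object`,
#'   `object_kind`, `provenance`), one row per parent pointer.
#' @export
derive_hierarchy_relations <- function(edition, lsid_map) {
  stopifnot(inherits(edition, "checklist_edition"))
  t <- edition$taxa
  uncovered <- setdiff(t$record_id, names(lsid_map))
  if (length(uncovered)) {
    abort_coverage(paste0("lsid_map does not cover record(s): ",
                          paste(head(uncovered, 10), collapse = ", ")))
  }
  child <- t$record_id[!is.na(t$parent_id)]
  parent <- t$parent_id[!is.na(t$parent_id)]
  tibble::tibble(
    subject = unname(lsid_map[parent]),
    type = rep("IsParentTaxonOf", length(child)),
    object = unname(lsid_map[child]),
    object_kind = rep("lsid", length(child)),
    provenance = rep(edition$edition_token, length(child))
  )
}

# Directed "data recorded against X applies to Y" edges: containment
# (X IsIncludedIn Y, equivalently Y Includes X) and congruence in both
# directions.  Overlaps licenses no transfer; hierarchy and name relations
# are excluded.
applicability_edges <- function(repo) {
  r <- repo$relations[repo$relations$object_kind == "lsid", , drop = FALSE]
  inc <- r[r$type == "IsIncludedIn", c("subject", "object")]
  inc2 <- r[r$type == "Includes", c("object", "subject")]
  names(inc2) <- c("subject", "object")
  cg <- r[r$type == "IsCongruentTo", c("subject", "object")]
  cg2 <- cg[, c("object", "subject")]
  names(cg2) <- c("subject", "object")
  rbind(inc, inc2, cg, cg2)
}

known_concepts <- function(repo) {
  r <- repo$relations
  conc <- r$type %in% .set_relations & r$object_kind == "lsid"
  unique(c(r$subject[r$type %in% .set_relations], r$object[conc]))
}

#' Concepts to which data recorded against a concept applies
#'
#' If concept `A` is contained within concept `B`, records (occurrences,
#' descriptions, properties) associated with `A` also apply to `B`.  This
#' computes the closure of `start` under `IsIncludedIn`/`Includes`
#' containment edges and `IsCongruentTo` equivalences.  `Overlaps` never
#' contributes (overlap licenses no record transfer), nor do hierarchy or
#' name relations.  Cyclic inputs terminate.
#'
#' @param repo An [lsid_repository()].
#' @param start LSID (or URN text) known to the repository.
#' @return Character vector of concept identifiers, including `start`.
#' @export
propagate_applicability <- function(repo, start) {
  stopifnot(inherits(repo, "lsid_repository"))
  start <- as_id_text(start)
  known <- known_concepts(repo)
  if (!start %in% known) {
    abort_lookup(paste0("Concept not known to repository: ", start))
  }
  e <- applicability_edges(repo)
  if (!nrow(e)) return(start)
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = unique(c(known, e$subject, e$object)))
  reach <- igraph::subcomponent(g, start, mode = "out")
  sort(unique(c(start, names(reach))), method = "radix")
}

#' Congruence classes of the repository
#'
#' Partition of all concepts known to the repository into connected
#' components of the (symmetric, transitively closed) `IsCongruentTo` graph.
#' Concepts without congruence edges form singleton classes.
#'
#' @param repo An [lsid_repository()].
#' @return A list of character vectors, each one class, ordered by their
#'   first member.
#' @export
congruence_classes <- function(repo) {
  stopifnot(inherits(repo, "lsid_repository"))
  known <- known_concepts(repo)
  if (!length(known)) return(list())
  r <- repo$relations
  cg <- r[r$type == "IsCongruentTo" & r$object_kind == "lsid",
          c("subject", "object"), drop = FALSE]
  g <- igraph::graph_from_data_frame(cg, directed = FALSE,
                                     vertices = unique(c(known, cg$subject, cg$object)))
  comp <- igraph::components(g)
  classes <- split(names(comp$membership), comp$membership)
  classes <- lapply(classes, sort, method = "radix")
  classes <- classes[order(vapply(classes, `[`, character(1), 1), method = "radix")]
  names(classes) <- NULL
  classes
}
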
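# Per-taxon TCS-style RDF/XML metadata documents, generated on demand from
# an edition plus the relation repository (the catalogue is never stored as
# one big TCS document), and a local resolver over a store of editions.
#
# Element and property names follow the TDWG ontology vocabulary
# (TaxonConcept, TaxonName, hasRelationship, relationshipCategory,
# publishedInCitation); the namespace URIs are configurable because the
# historical TDWG URIs may no longer resolve.

#' TCS export configuration
#'
#' @param ns_rdf,ns_tc,ns_tn Namespace URIs used for the `rdf:`, `tc:`
#'   (TaxonConcept vocabulary) and `tn:` (TaxonName vocabulary) prefixes.
#' @return A list of class `tcs_config`.
#' @export
tcs_config <- function(
    ns_rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    ns_tc = "http://rs.tdwg.org/ontology/voc/TaxonConcept#",
    ns_tn = "http://rs.tdwg.org/ontology/voc/TaxonName#") {
  structure(list(ns_rdf = ns_rdf, ns_tc = ns_tc, ns_tn = ns_tn),
            class = "tcs_config")
}

#' Build the TCS metadata document for one taxon concept
#'
#' The document's core element is a `tc:TaxonConcept` carrying
#' `rdf:about = <the LSID>`; each concept has a single accepted name,
#' embedded as a `tn:TaxonName` with its rank (and publication citation when
#' present).  Relationships are expressed through `tc:hasRelationship` /
#' `tc:Relationship` with a `tc:relationshipCategory`: one `HasSynonym` per
#' synonym, one `HasVernacular` per vernacular name, `IsChildTaxonOf` to the
#' parent concept, `IsParentTaxonOf` to each child, and - when the provider
#' supplied a GUID for the name - an anonymous `tc:TaxonConcept` (with no
#' name of its own) wrapping that GUID, linked by `IsCongruentTo`.  Stored
#' repository relations about the LSID (including derivable inverses) are
#' appended.
#'
#' @param lsid `lsid` object or URN text; must map to a record of `edition`
#'   via `lsid_map` (matched on the UUID, ignoring version).
#' @param edition A [checklist_edition()].
#' @param lsid_map Named character vector, record id to LSID text, covering
#'   the record and its parent/children.
#' @param repo Optional [lsid_repository()] with further relations.
#' @param config A [tcs_config()].
#' @return An object of class `metadata_document` with fields
#'   `core_concept_lsid`, `xml` (an `xml2` document) and
#'   `included_relations` (tibble `category`, `object`, `object_kind`).
#' @export
build_metadata_document <- function(lsid, edition, lsid_map, repo = NULL,
                                    config = tcs_config()) {
  stopifnot(inherits(edition, "checklist_edition"))
  lsid <- parse_lsid(lsid)
  urn <- compose_lsid(lsid)
  map_objects <- vapply(lsid_map, function(u) parse_lsid(u)$object_id,
                        character(1))
  i <- match(lsid$object_id, map_objects)
  if (is.na(i)) {
    abort_unknown_object(paste0("No record for object id '", lsid$object_id,
                                "' in edition '", edition$edition_token, "'"))
  }
  rec <- edition_record(edition, names(lsid_map)[i])

  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = config$ns_rdf,
    "xmlns:tc" = config$ns_tc,
    "xmlns:tn" = config$ns_tn
  )
  core <- xml2::xml_add_child(doc, "tc:TaxonConcept", "rdf:about" = urn)

  # single accepted name
  has_name <- xml2::xml_add_child(core, "tc:hasName")
  tname <- xml2::xml_add_child(has_name, "tn:TaxonName")
  xml2::xml_add_child(tname, "tn:nameComplete", rec$scientific_name)
  xml2::xml_add_child(tname, "tn:rankString", rec$rank)
  if (!is.na(rec$citation)) {
    xml2::xml_add_child(tname, "tn:publishedInCitation", rec$citation)
  }

  rel_rows <- list()
  add_rel <- function(category, to_resource = NULL, to_name = NULL,
                      lang = NULL, name_guid = NULL) {
    hr <- xml2::xml_add_child(core, "tc:hasRelationship")
    rel <- xml2::xml_add_child(hr, "tc:Relationship")
    xml2::xml_add_child(rel, "tc:relationshipCategory",
                        "rdf:resource" = paste0(config$ns_tc, category))
    if (!is.null(to_resource)) {
      xml2::xml_add_child(rel, "tc:toTaxon", "rdf:resource" = to_resource)
      rel_rows[[length(rel_rows) + 1L]] <<- tibble::tibble(
        category = category, object = to_resource, object_kind = "lsid")
    } else if (!is.null(name_guid)) {
      # anonymous TaxonConcept (no name of its own) wrapping the
      # provider-assigned name GUID
      tt <- xml2::xml_add_child(rel, "tc:toTaxon")
      anon <- xml2::xml_add_child(tt, "tc:TaxonConcept")
      xml2::xml_add_child(anon, "tc:hasName", "rdf:resource" = name_guid)
      rel_rows[[length(rel_rows) + 1L]] <<- tibble::tibble(
        category = category, object = name_guid, object_kind = "name_guid")
    } else {
      tt <- xml2::xml_add_child(rel, "tc:toTaxon")
      nm <- xml2::xml_add_child(tt, "tn:TaxonName")
      nc <- xml2::xml_add_child(nm, "tn:nameComplete", to_name)
      if (!is.null(lang) && !is.na(lang)) {
        xml2::xml_set_attr(nc, "xml:lang", lang)
      }
      rel_rows[[length(rel_rows) + 1L]] <<- tibble::tibble(
        category = category, object = to_name, object_kind = "name")
    }
  }

  for (s in rec$synonyms[[1]]) add_rel("HasSynonym", to_name = s)
  vl <- rec$vernacular_lang[[1]]
  vs <- rec$vernaculars[[1]]
  for (j in seq_along(vs)) {
    add_rel("HasVernacular", to_name = vs[j],
            lang = if (j <= length(vl)) vl[j] else NA)
  }

  if (!is.na(rec$parent_id) && rec$parent_id %in% names(lsid_map)) {
    add_rel("IsChildTaxonOf", to_resource = unname(lsid_map[[rec$parent_id]]))
  }
  kids <- edition$taxa$record_id[!is.na(edition$taxa$parent_id) &
                                   edition$taxa$parent_id == rec$record_id]
  for (k in kids) {
    if (k %in% names(lsid_map)) {
      add_rel("IsParentTaxonOf", to_resource = unname(lsid_map[[k]]))
    }
  }

  if (!is.na(rec$provider_name_guid)) {
    add_rel("IsCongruentTo", name_guid = rec$provider_name_guid)
  }
  if (!is.na(rec$provider_taxon_guid)) {
    add_rel("IsCongruentTo", to_resource = rec$provider_taxon_guid)
  }

  if (!is.null(repo)) {
    # relations may be stored against any edition's version of this concept
    extra <- do.call(rbind, lapply(repo_aliases(repo, lsid),
                                   function(a) relations_about(repo, a)))
    extra <- extra[!duplicated(paste(extra$type, extra$object, sep = "\x1f")), ,
                   drop = FALSE]
    seen <- if (length(rel_rows)) do.call(rbind, rel_rows) else NULL
    for (k in seq_len(nrow(extra))) {
      dup <- !is.null(seen) &&
        any(seen$category == extra$type[k] & seen$object == extra$object[k])
      if (dup) next
      if (extra$object_kind[k] == "name_guid") {
        add_rel(extra$type[k], name_guid = extra$object[k])
      } else {
        add_rel(extra$type[k], to_resource = extra$object[k])
      }
      seen <- do.call(rbind, rel_rows)
    }
  }

  structure(
    list(
      core_concept_lsid = lsid,
      xml = doc,
      included_relations = if (length(rel_rows)) {
        tibble::as_tibble(do.call(rbind, rel_rows))
      } else {
        tibble::tibble(category = character(), object = character(),
                       object_kind = character())
      }
    ),
    class = "metadata_document"
  )
}

#' @export
print.metadata_document <- function(x, ...) {
  cat("<metadata_document> ", compose_lsid(x$core_concept_lsid), " (",
      nrow(x$included_relations), " relation(s))\n", sep = "")
  invisible(x)
}

#' Serialised XML text of a metadata document
#'
#' @param doc A `metadata_document` from [build_metadata_document()].
#' @return A single character string of RDF/XML.
#' @export
tcs_xml_text <- function(doc) {
  stopifnot(inherits(doc, "metadata_document"))
  as.character(doc$xml)
}

# ---------------------------------------------------------------------------

#' Bundle editions, LSID maps and a relation repository into a store
#'
#' @param editions List of [checklist_edition()] objects, oldest first.
#' @param maps List (same length/order) of named character LSID maps, one per
#'   edition.
#' @param repo Optional [lsid_repository()].
#' @return An object of class `lsid_store`.
#' @seealso [resolve_local()]
#' @export
lsid_store <- function(editions, maps, repo = NULL) {
  stopifnot(length(editions) == length(maps), length(editions) >= 1L)
  tokens <- vapply(editions, function(e) e$edition_token, character(1))
  for (i in seq_along(editions)) {
    uncovered <- setdiff(editions[[i]]$taxa$record_id, names(maps[[i]]))
    if (length(uncovered)) {
      abort_coverage(paste0("LSID map for edition '", tokens[i],
                            "' does not cover record(s): ",
                            paste(head(uncovered, 10), collapse = ", ")))
    }
  }
  structure(list(editions = stats::setNames(editions, tokens),
                 maps = stats::setNames(maps, tokens),
                 tokens = tokens, repo = repo),
            class = "lsid_store")
}

#' Resolve an LSID against a local store
#'
#' An LSID with a version resolves against exactly that edition.  A
#' versionless LSID resolves to the most recent edition containing its UUID.
#' An LSID whose UUID occurs only in superseded editions (a deprecated
#' concept) still resolves, to its last edition's document - deprecated
#' concepts stay accessible in perpetuity - enriched with any repository
#' relations linking it to current concepts.
#'
#' @param lsid_text LSID URN text (or `lsid` object).
#' @param store An [lsid_store()].
#' @param config A [tcs_config()].
#' @return A `metadata_document`.
#' @export
resolve_local <- function(lsid_text, store, config = tcs_config()) {
  stopifnot(inherits(store, "lsid_store"))
  l <- parse_lsid(lsid_text)
  containing <- character()
  for (tok in store$tokens) {
    objs <- vapply(store$maps[[tok]], function(u) parse_lsid(u)$object_id,
                   character(1))
    if (l$object_id %in% objs) containing <- c(containing, tok)
  }
  if (!length(containing)) {
    abort_unknown_object(paste0("Unknown object id: ", l$object_id))
  }
  tok <- if (is.null(l$version)) {
    tail(containing, 1)  # most recent edition containing the concept
  } else {
    if (!l$version %in% containing) {
      abort_unknown_version(paste0(
        "Object id '", l$object_id, "' is known, but not under version '",
        l$version, "' (known: ", paste(containing, collapse = ", "), ")"
      ))
    }
    l$version
  }
  # the core element carries the edition's own (versioned) LSID, so a
  # versionless request still yields a fully versioned document
  map <- store$maps[[tok]]
  objs <- vapply(map, function(u) parse_lsid(u)$object_id, character(1))
  core <- parse_lsid(map[[match(l$object_id, objs)]])
  build_metadata_document(core, store$editions[[tok]], map,
                          repo = store$repo, config = config)
}

# ---------------------------------------------------------------------------

#' Provider GUID attributes for the Common Data Model
#'
#' Emits the `TAXONLSID` / `NAMELSID` attribute pair a provider wrapper would
#' expose: for an accepted name both attributes may be present (concept GUID
#' and name GUID); for a synonym only `NAMELSID` is permitted.  GUIDs the
#' record does not carry are simply absent.
#'
#' @param record One-row slice of an edition's `taxa` tibble (or the list
#'   returned by indexing it).
#' @param role `"accepted"` (default) or `"synonym"`.
#' @return Named character vector with entries `TAXONLSID` and/or
#'   `NAMELSID`; empty when the record carries no GUIDs.
#' @export
write_cdm_attributes <- function(record, role = c("accepted", "synonym")) {
  role <- match.arg(role)
  record <- as.list(record)
  out <- character()
  if (role == "accepted" && !is.na(record$provider_taxon_guid)) {
    out[["TAXONLSID"]] <- record$provider_taxon_guid
  }
  if (!is.na(record$provider_name_guid)) {
    out[["NAMELSID"]] <- record$provider_name_guid
  }
  out
}
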
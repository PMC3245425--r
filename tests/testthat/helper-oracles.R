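# Shared helpers: tiny hand-built editions, an LSID-map minting shortcut,
# and independent oracles (brute-force all-pairs matcher, breadth-first
# reachability, union-find) against which the package's algorithms are
# checked.

make_taxa_row <- function(record_id, name, rank, parent = NA_character_,
                          status = "accepted", distribution = NA_character_,
                          provider = NA_character_,
                          taxon_guid = NA_character_, name_guid = NA_character_,
                          citation = NA_character_,
                          synonyms = character(), vernaculars = character(),
                          vlang = character()) {
  tibble::tibble(
    record_id = record_id, scientific_name = name, rank = rank,
    status = status, parent_id = parent, distribution = distribution,
    provider_id = provider, provider_taxon_guid = taxon_guid,
    provider_name_guid = name_guid, citation = citation,
    synonyms = list(synonyms), vernaculars = list(vernaculars),
    vernacular_lang = list(vlang)
  )
}

# A minimal well-formed edition: kingdom > family > genus > 2 species.
tiny_edition <- function(token = "ed1") {
  checklist_edition(rbind(
    make_taxa_row("k1", "Plantae", "kingdom"),
    make_taxa_row("f1", "Rosaceae", "family", "k1"),
    make_taxa_row("g1", "Rosa", "genus", "f1"),
    make_taxa_row("s1", "Rosa alba L.", "species", "g1",
                  distribution = "Europe", provider = "p:1",
                  synonyms = c("Rosa candida Hort."),
                  vernaculars = c("white rose"), vlang = c("en")),
    make_taxa_row("s2", "Rosa canina L.", "species", "g1",
                  distribution = "Europe; Asia-Temperate", provider = "p:2")
  ), token)
}

# Mint one LSID per record of an edition; returns named character map.
mint_map <- function(edition, minter, version = edition$edition_token,
                     authority = "catalogueoflife.org", namespace = "taxon") {
  ids <- edition$taxa$record_id
  stats::setNames(vapply(ids, function(i) {
    compose_lsid(lsid(mint_object_id(minter), version = version,
                      authority = authority, namespace = namespace))
  }, character(1)), ids)
}

# Brute-force all-pairs matching oracle.  Compares raw field tuples directly
# (no canonical-string encoding, no sorting trick): two records are equal iff
# every compared field is equal.  Duplicate-signature groups on either side
# are left unmatched, as the matcher is required to do.
oracle_match <- function(old, new) {
  tuple <- function(ed, i) {
    t <- ed$taxa
    if (is_species_level(t$rank[i])) {
      list(kind = "sp", name = t$scientific_name[i],
           syn = sort(unique(t$synonyms[[i]])),
           vern = sort(unique(t$vernaculars[[i]])),
           dist = t$distribution[i], prov = t$provider_id[i])
    } else {
      list(kind = "hi", name = t$scientific_name[i],
           lin = lineage(ed, t$record_id[i]))
    }
  }
  to <- lapply(seq_len(nrow(old$taxa)), function(i) tuple(old, i))
  tn <- lapply(seq_len(nrow(new$taxa)), function(i) tuple(new, i))
  eq <- function(a, b) identical(a, b)
  n_old <- length(to); n_new <- length(tn)
  hits <- matrix(FALSE, n_old, n_new)
  for (i in seq_len(n_old)) {
    for (j in seq_len(n_new)) hits[i, j] <- eq(to[[i]], tn[[j]])
  }
  dup_old <- logical(n_old)
  for (i in seq_len(n_old)) {
    for (i2 in seq_len(n_old)) {
      if (i != i2 && eq(to[[i]], to[[i2]])) dup_old[i] <- TRUE
    }
  }
  dup_new <- logical(n_new)
  for (j in seq_len(n_new)) {
    for (j2 in seq_len(n_new)) {
      if (j != j2 && eq(tn[[j]], tn[[j2]])) dup_new[j] <- TRUE
    }
  }
  pairs_old <- character(); pairs_new <- character()
  for (i in seq_len(n_old)) {
    js <- which(hits[i, ])
    if (length(js) == 1L && !dup_old[i] && !dup_new[js]) {
      pairs_old <- c(pairs_old, old$taxa$record_id[i])
      pairs_new <- c(pairs_new, new$taxa$record_id[js])
    }
  }
  list(
    pairs = tibble::tibble(old_id = pairs_old, new_id = pairs_new),
    unmatched_old = sort(setdiff(old$taxa$record_id, pairs_old)),
    unmatched_new = sort(setdiff(new$taxa$record_id, pairs_new))
  )
}

# Breadth-first reachability oracle over an explicit edge list.
oracle_bfs <- function(edges_from, edges_to, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(edges_to[edges_from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen, method = "radix")
}

# Union-find oracle for congruence classes.
oracle_union_find <- function(vertices, edges_a, edges_b) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(vertices, find, character(1))
  cl <- split(vertices, roots)
  cl <- lapply(cl, sort, method = "radix")
  cl <- cl[order(vapply(cl, `[`, character(1), 1), method = "radix")]
  names(cl) <- NULL
  cl
}

# Random relation repository over `n` synthetic concept LSIDs; returns the
# repo plus the raw edge list for oracle use.
random_relation_repo <- function(n = 50, p_incl = 0.03, p_cong = 0.02) {
  minter <- lsid_minter(sample.int(1e6, 1))
  ids <- vapply(seq_len(n), function(i) {
    compose_lsid(lsid(mint_object_id(minter)))
  }, character(1))
  repo <- lsid_repository()
  subj <- character(); typ <- character(); obj <- character()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- stats::runif(1)
      if (r < p_incl) {
        typ <- c(typ, sample(c("IsIncludedIn", "Includes"), 1))
        subj <- c(subj, ids[i]); obj <- c(obj, ids[j])
      } else if (r < p_incl + p_cong) {
        typ <- c(typ, "IsCongruentTo")
        subj <- c(subj, ids[i]); obj <- c(obj, ids[j])
      }
    }
  }
  # a few Overlaps edges that must never contribute to applicability
  if (n >= 4) {
    subj <- c(subj, ids[1]); typ <- c(typ, "Overlaps"); obj <- c(obj, ids[2])
  }
  for (k in seq_along(subj)) {
    repo <- add_relation(repo, subj[k], typ[k], obj[k])
  }
  list(repo = repo, ids = ids,
       edges = tibble::tibble(subject = subj, type = typ, object = obj))
}

expect_same_match <- function(m, oracle) {
  expect_setequal(paste(m$pairs$old_id, m$pairs$new_id),
                  paste(oracle$pairs$old_id, oracle$pairs$new_id))
  expect_identical(m$unmatched_old, oracle$unmatched_old)
  expect_identical(m$unmatched_new, oracle$unmatched_new)
}
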
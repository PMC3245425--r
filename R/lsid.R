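# Life Science Identifiers: urn:lsid:<authority>:<namespace>:<object>[:<version>]
# The object part is a UUID; the optional version part carries the edition
# token, so one concept keeps one UUID across editions and only the version
# changes while the underlying concept is unchanged.

.uuid_regex <- "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$"

#' Construct an LSID
#'
#' @param object_id UUID text (8-4-4-4-12 hexadecimal groups).
#' @param version Optional version token (e.g. an edition token such as
#'   `"ac2008"`); `NULL` for an unversioned LSID.
#' @param authority DNS name of the issuing authority.
#' @param namespace Namespace token within the authority.
#' @return An object of class `lsid`.
#' @seealso [parse_lsid()], [compose_lsid()], [same_concept()]
#' @export
lsid <- function(object_id, version = NULL,
                 authority = "catalogueoflife.org", namespace = "taxon") {
  out <- structure(
    list(authority = authority, namespace = namespace,
         object_id = object_id, version = version),
    class = "lsid"
  )
  check_lsid_components(out, abort_compose)
  out
}

check_lsid_components <- function(x, fail) {
  parts <- c(x$authority, x$namespace, x$object_id, x$version)
  if (any(!nzchar(parts))) fail("LSID components must be non-empty")
  if (any(grepl(":", parts, fixed = TRUE))) {
    fail("LSID components must not contain ':'")
  }
  if (!grepl(.uuid_regex, x$object_id)) {
    fail(paste0("Object id is not a well-formed UUID: '", x$object_id, "'"))
  }
  invisible(x)
}

#' Parse an LSID from text
#'
#' Splits a `urn:lsid:` URN into authority, namespace, UUID object id and
#' optional version.  Components are kept verbatim, so
#' `compose_lsid(parse_lsid(x))` reproduces `x` byte for byte.
#'
#' @param text A single LSID string.
#' @return An object of class `lsid`.
#' @export
parse_lsid <- function(text) {
  if (inherits(text, "lsid")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || tolower(parts[1]) != "urn" || tolower(parts[2]) != "lsid") {
    abort_parse(paste0("Not an 'urn:lsid:' URN: '", text, "'"))
  }
  if (!(length(parts) %in% c(5L, 6L))) {
    abort_parse(paste0(
      "An LSID has 5 or 6 colon-separated components ",
      "(urn:lsid:authority:namespace:object[:version]); got ", length(parts)
    ))
  }
  if (any(!nzchar(parts))) {
    abort_parse(paste0("Empty component in LSID: '", text, "'"))
  }
  if (!grepl(.uuid_regex, parts[5])) {
    abort_parse(paste0("Object id is not a well-formed UUID: '", parts[5], "'"))
  }
  structure(
    list(authority = parts[3], namespace = parts[4], object_id = parts[5],
         version = if (length(parts) == 6L) parts[6] else NULL),
    class = "lsid"
  )
}

#' Compose an LSID to its URN text
#'
#' The trailing `:` is omitted when no version is present;
#' `parse_lsid(compose_lsid(l))` recovers `l`.
#'
#' @param x An `lsid` object.
#' @return A single character string.
#' @export
compose_lsid <- function(x) {
  stopifnot(inherits(x, "lsid"))
  check_lsid_components(x, abort_compose)
  base <- paste("urn:lsid", x$authority, x$namespace, x$object_id, sep = ":")
  if (is.null(x$version)) base else paste(base, x$version, sep = ":")
}

#' @export
format.lsid <- function(x, ...) compose_lsid(x)

#' @export
print.lsid <- function(x, ...) {
  cat("<lsid> ", compose_lsid(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.lsid <- function(x, ...) compose_lsid(x)

#' Do two LSIDs identify the same taxon concept?
#'
#' True iff authority (case-insensitively: DNS names are case-insensitive),
#' namespace and UUID object id are equal.  The version field is ignored: the
#' same UUID under `:ac2008` and `:ac2009` is the same unchanged concept.  No
#' network resolution is performed.
#'
#' @param a,b `lsid` objects or LSID strings.
#' @return Logical scalar.
#' @export
same_concept <- function(a, b) {
  a <- parse_lsid(a)
  b <- parse_lsid(b)
  tolower(a$authority) == tolower(b$authority) &&
    a$namespace == b$namespace &&
    a$object_id == b$object_id
}

# ---------------------------------------------------------------------------
# Seeded UUID minter.  Object ids are random version-4-style UUIDs; a fixed
# seed makes the minted sequence reproducible, and the minter's RNG stream is
# isolated from the global .Random.seed.

#' Create a seedable UUID minter
#'
#' Mints random version-4-style UUIDs for use as LSID object ids.  The minter
#' owns a private RNG stream initialised from `seed`, so the sequence of
#' minted ids is reproducible and independent of the global random state.
#' Ids already issued by the minter are never issued again within its
#' lifetime.
#'
#' @param seed Integer seed.
#' @return An object of class `lsid_minter`.
#' @seealso [mint_object_id()]
#' @export
lsid_minter <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  e$issued <- new.env(parent = emptyenv(), hash = TRUE)
  e$retries <- 0L
  class(e) <- "lsid_minter"
  e
}

with_minter_rng <- function(minter, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", minter$state, envir = globalenv())
  on.exit({
    minter$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Mint a fresh UUID object id
#'
#' @param minter An [lsid_minter()].
#' @param avoid Character vector of object ids that must not be reissued
#'   (e.g. every id already present in an LSID map).  A collision triggers a
#'   silent retry; retries are counted in `minter$retries`.
#' @return A UUID string in 8-4-4-4-12 form.
#' @export
mint_object_id <- function(minter, avoid = character()) {
  stopifnot(inherits(minter, "lsid_minter"))
  hex <- c(0:9, letters[1:6])
  repeat {
    u <- with_minter_rng(minter, {
      d <- sample(hex, 32L, replace = TRUE)
      d[13] <- "4"                       # version nibble
      d[17] <- sample(c("8", "9", "a", "b"), 1L)  # variant nibble
      paste0(
        paste(d[1:8], collapse = ""), "-", paste(d[9:12], collapse = ""), "-",
        paste(d[13:16], collapse = ""), "-", paste(d[17:20], collapse = ""),
        "-", paste(d[21:32], collapse = "")
      )
    })
    if (is.null(minter$issued[[u]]) && !(u %in% avoid)) {
      minter$issued[[u]] <- TRUE
      return(u)
    }
    minter$retries <- minter$retries + 1L
  }
}

# ---------------------------------------------------------------------------
# LSID map files: TSV with columns record_id, lsid (one row per taxon).

#' Read or write an LSID map
#'
#' An LSID map pairs each record id of one edition with its LSID.  On disk it
#' is a two-column TSV (`record_id`, `lsid`).
#'
#' @param path File path.
#' @return `read_lsid_map()`: a named character vector (names are record
#'   ids, values LSID strings).
#' @export
read_lsid_map <- function(path) {
  d <- read.delim(path, sep = "\t", colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("record_id", "lsid") %in% names(d))) {
    abort_format("LSID map needs columns 'record_id' and 'lsid'")
  }
  stats::setNames(d$lsid, d$record_id)
}

#' @rdname read_lsid_map
#' @param map Named character vector (record_id -> LSID text).
#' @export
write_lsid_map <- function(map, path) {
  d <- data.frame(record_id = names(map), lsid = unname(map),
                  stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
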
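#' Worked-example checklist fixtures
#'
#' Small hand-encoded checklist editions shipped with the package,
#' reconstructing classic published worked examples of taxon-concept change
#' and concept metadata:
#'
#' * `droseraceae_2008` / `droseraceae_2009` - extracts of the Droseraceae
#'   classification (order Nepenthales) as it stood in the 2008 and 2009
#'   Annual Checklist editions.  In 2008 *Drosera tracyi* is a species with
#'   *Drosera filiformis* var. *tracyi* as a synonym; in 2009 the two
#'   concepts are lumped, so the variety is the accepted name and
#'   *Drosera tracyi* survives only as its synonym.  The 2009 extract adds
#'   the genera *Aldrovanda* and *Drosophyllum*.
#' * `abrus` - the legume *Abrus precatorius* L. with one synonym
#'   (*Abrus tunguensis*), vernacular names including "crab's eye", its
#'   parent genus *Abrus* and child subspecies *africanus*: the canonical
#'   resolver-metadata example.
#' * `piptocephalis` - the fungus *Piptocephalis pseudocephala*, supplied by
#'   a provider (Index Fungorum) that issues its own name LSIDs; the record
#'   carries a provider name GUID.  The numeric part of that GUID is
#'   synthetic.
#' * `aldrovanda` - *Aldrovanda vesiculosa* L. with its two synonyms
#'   (*Aldrovanda verticillata* Roxb., *Drosera aldrovanda* F. Muell.), the
#'   thesaurus-expansion example.
#'
#' Details the published extracts leave unstated (authorship strings, the
#' fourth *Drosera* species, provider dataset ids) are filled in with
#' plausible synthetic values; provider identifiers are kept identical
#' across the two Droseraceae editions so that only the genuinely changed
#' concepts differ.
#'
#' @param name One of `"droseraceae_2008"`, `"droseraceae_2009"`, `"abrus"`,
#'   `"piptocephalis"`, `"aldrovanda"`.
#' @return A [checklist_edition()].
#' @export
paper_fixture <- function(name) {
  tokens <- c(droseraceae_2008 = "ac2008", droseraceae_2009 = "ac2009",
              abrus = "ac2008", piptocephalis = "ac2008",
              aldrovanda = "ac2008")
  if (length(name) != 1L || !name %in% names(tokens)) {
    abort_lookup(paste0("Unknown fixture name '", paste(name, collapse = ","),
                        "'; available: ", paste(names(tokens), collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "taxcat",
                      mustWork = TRUE)
  read_checklist(path, edition_token = tokens[[name]])
}
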
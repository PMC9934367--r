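#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn :=
#' @importFrom dplyr %>%
NULL

# Canonical subunit order used for all keys; Db1 is the essential beta subunit
# without which no combination expresses functionally.
SUBUNIT_ORDER <- c("Da1", "Da2", "Da3", "Da4", "Db1", "Db2", "Db3")
SUBUNIT_GREEK <- c(
  Da1 = "Dα1", Da2 = "Dα2", Da3 = "Dα3", Da4 = "Dα4",
  Db1 = "Dβ1", Db2 = "Dβ2", Db3 = "Dβ3"
)

#' Recognized nAChR subunit identifiers
#'
#' The subunit universe covered by the panel: the Drosophila melanogaster
#' alpha subunits Da1-Da4 and beta subunits Db1-Db3 (rendered as Greek
#' "Dα1" ... "Dβ3" for display). Identifiers are stored
#' ASCII-normalized ("Da1", "Db1") to keep CSV round-trips encoding-safe.
#'
#' @return Character vector of the seven subunit identifiers in canonical
#'   order.
#' @export
#' @examples
#' nachr_subunits()
nachr_subunits <- function() SUBUNIT_ORDER

normalize_subunit_token <- function(token) {
  x <- gsub("α", "a", token, fixed = TRUE)
  x <- gsub("β", "b", x, fixed = TRUE)
  x <- tolower(trimws(x))
  x <- sub("^d", "D", x)
  x
}

#' Parse a subunit combination
#'
#' Parses a "/"-separated receptor label such as `"Da1/Db1"` or
#' `"Dα1/Dβ1"` into a canonical set of subunit identifiers.
#' Greek (`α`, `β`) and ASCII (`a`, `b`) spellings and any letter
#' case are accepted; member order is irrelevant.
#'
#' @param text A single receptor label, subunits separated by `/`.
#' @return Character vector of ASCII subunit identifiers in canonical order.
#' @export
#' @examples
#' parse_subunits("Dβ1/Dα1")  # same set as "Da1/Db1"
#' parse_subunits("Da3/Db1")
parse_subunits <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(text, "/", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) {
    abort("Empty subunit set: a receptor must contain at least one subunit.")
  }
  norm <- vapply(normalize_subunit_token(tokens), function(tok) {
    hit <- SUBUNIT_ORDER[tolower(SUBUNIT_ORDER) == tolower(tok)]
    if (length(hit) != 1L) NA_character_ else hit
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(norm)) {
    bad <- tokens[is.na(norm)]
    abort(paste0(
      "Unknown subunit name(s): ", paste(sQuote(bad), collapse = ", "),
      ". Recognized subunits: ", paste(SUBUNIT_ORDER, collapse = ", "), "."
    ))
  }
  if (anyDuplicated(norm)) {
    dup <- unique(norm[duplicated(norm)])
    abort(paste0("Duplicate subunit(s) in set: ", paste(dup, collapse = ", "), "."))
  }
  norm[order(match(norm, SUBUNIT_ORDER))]
}

#' Canonical receptor key
#'
#' Serializes a set of subunits (or a receptor label in any accepted
#' spelling) to the canonical "/"-joined ASCII form used as a stable key
#' throughout the package. `parse_subunits(subunit_key(x))` round-trips.
#'
#' @param x Character vector of subunit identifiers, or a single "/"-joined
#'   label.
#' @return The canonical key, e.g. `"Da1/Db1"`.
#' @export
#' @examples
#' subunit_key(c("Db1", "Da1"))
#' subunit_key("Dβ1/Dα1")
subunit_key <- function(x) {
  members <- if (length(x) == 1L && grepl("/", x)) parse_subunits(x) else {
    parse_subunits(paste(x, collapse = "/"))
  }
  paste(members, collapse = "/")
}

#' Display form of a receptor key
#'
#' Renders canonical ASCII subunit identifiers with Greek letters for
#' figures and tables (e.g. `"Da1/Db1"` becomes `"Dα1/Dβ1"`).
#'
#' @param key Character vector of canonical receptor keys or subunit ids.
#' @return Character vector with Greek-letter subunit names.
#' @export
format_subunits <- function(key) {
  vapply(key, function(k) {
    members <- strsplit(k, "/", fixed = TRUE)[[1]]
    paste(ifelse(members %in% names(SUBUNIT_GREEK),
                 SUBUNIT_GREEK[members], members), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a subunit combination functional?
#'
#' A combination can only assemble into a functional receptor when it
#' contains the essential Db1 subunit; combinations lacking it do not
#' express measurable currents.
#'
#' @param receptor Character vector of receptor keys.
#' @return Logical vector.
#' @export
#' @examples
#' is_functional_receptor(c("Da1/Db1", "Da1/Da2"))
is_functional_receptor <- function(receptor) {
  vapply(receptor, function(k) "Db1" %in% parse_subunits(k), logical(1),
         USE.NAMES = FALSE)
}

#' Subunit presence indicators for a set of receptors
#'
#' Expands receptor keys into binary presence columns, one per requested
#' subunit — the covariate encoding used by the factor model and the CHAID
#' tree.
#'
#' @param receptor Character vector of receptor keys.
#' @param subunits Subunits to encode (default: the four that vary across
#'   the core panel).
#' @return A tibble with column `receptor` plus one 0/1 integer column per
#'   subunit.
#' @export
#' @examples
#' subunit_presence(c("Da1/Db1", "Da3/Db1/Db2"))
subunit_presence <- function(receptor,
                             subunits = c("Da1", "Da2", "Da3", "Db2")) {
  subunits <- vapply(subunits, subunit_key, character(1), USE.NAMES = FALSE)
  rows <- lapply(receptor, function(k) {
    members <- parse_subunits(k)
    stats::setNames(as.list(as.integer(subunits %in% members)), subunits)
  })
  dplyr::bind_cols(
    tibble::tibble(receptor = vapply(receptor, subunit_key, character(1),
                                     USE.NAMES = FALSE)),
    dplyr::bind_rows(rows)
  )
}

# Ligand enumeration ---------------------------------------------------------

LIGAND_LEVELS <- c("ACh", "imidacloprid", "thiacloprid", "clothianidin")

#' Ligands of the agonist panel
#'
#' The reference full agonist (acetylcholine, ACh) and the three
#' neonicotinoids assayed against every receptor. ACh defines the
#' normalization: every efficacy (Imax) is a fraction of the maximal ACh
#' response, so ACh itself has Imax = 1 by construction.
#'
#' @return Character vector of ligand names, reference first.
#' @export
nachr_ligands <- function() LIGAND_LEVELS

#' @rdname nachr_ligands
#' @export
reference_ligand <- function() LIGAND_LEVELS[1]

as_ligand_factor <- function(ligand, levels = LIGAND_LEVELS) {
  extra <- setdiff(unique(as.character(ligand)), levels)
  factor(as.character(ligand), levels = c(levels, extra))
}
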
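#' Parse a scientific-name string
#'
#' Splits a checklist name into genus, specific epithet, optional
#' infraspecific epithet, and (for deliberately pooled entries such as
#' `"Colias eurytheme/philodice"`) the ordered conglomerate components.
#' Monitoring-program checklists use four shapes: a bare genus, a binomial,
#' a trinomial (subspecies), and a slash conglomerate pooling two or more
#' congeneric epithets that volunteers cannot reliably separate in the field.
#'
#' Matching elsewhere in the package is case-insensitive and
#' whitespace-normalized, but the original string is kept in `raw` because
#' program spellings are sanctioned and must survive round trips.
#'
#' @param x Character vector of name strings.
#' @param genus_context Optional genus name used to expand abbreviated
#'   genera such as `"C. ladon"`. Abbreviations without a context are an
#'   error: a mapping file must be unambiguous.
#' @return A tibble with one row per input and columns `raw`, `genus`,
#'   `epithet`, `infraspecific`, `conglomerate` (list column of component
#'   epithets, `character(0)` unless the name pools several), and `rank`
#'   (one of `"genus"`, `"species"`, `"subspecies"`, `"conglomerate"`).
#' @examples
#' parse_scientific_name("Celastrina ladon/neglecta")
#' parse_scientific_name("Speyeria cybele leto")
#' @export
parse_scientific_name <- function(x, genus_context = NULL) {
  stopifnot(is.character(x))
  rows <- lapply(x, parse_one_name, genus_context = genus_context)
  tibble::new_tibble(list(
    raw = vapply(rows, `[[`, character(1), "raw"),
    genus = vapply(rows, `[[`, character(1), "genus"),
    epithet = vapply(rows, `[[`, character(1), "epithet"),
    infraspecific = vapply(rows, `[[`, character(1), "infraspecific"),
    conglomerate = lapply(rows, `[[`, "conglomerate"),
    rank = vapply(rows, `[[`, character(1), "rank")
  ), nrow = length(rows))
}

parse_one_name <- function(raw, genus_context = NULL) {
  if (is.na(raw)) stop("name is NA", call. = FALSE)
  squashed <- gsub("[[:space:]]+", " ", trimws(raw))
  if (!nzchar(squashed)) {
    stop("cannot parse an empty name string", call. = FALSE)
  }
  tokens <- strsplit(squashed, " ", fixed = TRUE)[[1]]

  genus <- tokens[[1]]
  if (grepl("^[A-Za-z]\\.$", genus)) {
    if (is.null(genus_context)) {
      stop("abbreviated genus '", genus, "' needs a genus context to expand",
           call. = FALSE)
    }
    if (toupper(substr(genus_context, 1, 1)) != toupper(substr(genus, 1, 1))) {
      stop("abbreviation '", genus, "' does not match context genus '",
           genus_context, "'", call. = FALSE)
    }
    genus <- genus_context
  }
  if (grepl("/", genus, fixed = TRUE)) {
    stop("cross-genus conglomerates are not supported: '", raw, "'",
         call. = FALSE)
  }
  if (!grepl("^[A-Za-z][A-Za-z-]*$", genus)) {
    stop("malformed genus in '", raw, "'", call. = FALSE)
  }
  genus <- paste0(toupper(substr(genus, 1, 1)), tolower(substr(genus, 2, nchar(genus))))

  epithets <- tokens[-1]
  if (length(epithets) > 2) {
    stop("too many name tokens in '", raw, "'", call. = FALSE)
  }
  bad <- epithets[!grepl("^[A-Za-z][A-Za-z/-]*$", epithets)]
  if (length(bad) > 0) {
    stop("malformed epithet '", bad[[1]], "' in '", raw, "'", call. = FALSE)
  }
  epithets <- tolower(epithets)

  congl <- character(0)
  epithet <- ""
  infraspecific <- ""
  if (length(epithets) == 0) {
    rank <- "genus"
  } else if (grepl("/", epithets[[1]], fixed = TRUE)) {
    if (length(epithets) > 1) {
      stop("conglomerate with trailing tokens in '", raw, "'", call. = FALSE)
    }
    congl <- strsplit(epithets[[1]], "/", fixed = TRUE)[[1]]
    congl <- congl[nzchar(congl)]
    if (length(congl) < 2) {
      stop("conglomerate needs at least two components in '", raw, "'",
           call. = FALSE)
    }
    rank <- "conglomerate"
  } else if (length(epithets) == 1) {
    epithet <- epithets[[1]]
    rank <- "species"
  } else {
    if (grepl("/", epithets[[2]], fixed = TRUE)) {
      stop("conglomerate below species rank is not supported in '", raw, "'",
           call. = FALSE)
    }
    epithet <- epithets[[1]]
    infraspecific <- epithets[[2]]
    rank <- "subspecies"
  }

  list(
    raw = raw,
    genus = genus,
    epithet = epithet,
    infraspecific = infraspecific,
    conglomerate = congl,
    rank = rank
  )
}

#' Canonical single-space form of a parsed name
#'
#' Deterministic `"Genus epithet[/epithet2...][ infraspecific]"` rendering.
#' Re-parsing the canonical string gives back the same parsed fields, so the
#' canonical form is the lookup key used throughout the package.
#'
#' @param parsed A tibble from [parse_scientific_name()] (or a character
#'   vector, which is parsed first).
#' @return Character vector of canonical name strings.
#' @examples
#' canonical_string("Celastrina  ladon")
#' @export
canonical_string <- function(parsed) {
  if (is.character(parsed)) parsed <- parse_scientific_name(parsed)
  purrr::pmap_chr(
    list(parsed$genus, parsed$epithet, parsed$infraspecific, parsed$conglomerate),
    function(genus, epithet, infra, congl) {
      if (length(congl) > 0) {
        paste0(genus, " ", paste(congl, collapse = "/"))
      } else if (!nzchar(epithet)) {
        genus
      } else if (nzchar(infra)) {
        paste(genus, epithet, infra)
      } else {
        paste(genus, epithet)
      }
    }
  )
}

# canonical key for case-insensitive lookup
canonical_key <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

#' Edit distance between two epithets
#'
#' Plain Levenshtein distance (unit insert/delete/substitute costs), used by
#' the checklist aligner to propose spelling-deviation candidates such as
#' "edwardsi" vs "edwardsii".
#'
#' @param a,b Character vectors of lowercase epithets, recycled to a common
#'   length.
#' @return Integer vector of distances.
#' @examples
#' epithet_distance("edwardsi", "edwardsii")
#' @export
epithet_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  as.integer(mapply(function(x, y) utils::adist(x, y)[1, 1], a, b,
                    USE.NAMES = FALSE))
}

# species-level binomial of a parsed row ("" when genus-rank)
species_binomial <- function(parsed) {
  purrr::pmap_chr(
    list(parsed$genus, parsed$epithet, parsed$conglomerate),
    function(genus, epithet, congl) {
      if (length(congl) > 0 || !nzchar(epithet)) "" else paste(genus, epithet)
    }
  )
}
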
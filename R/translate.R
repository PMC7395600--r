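zero_message <- "There is no match in this list (species presumed absent)"

#' Translate a taxon name from one monitoring program to another
#'
#' Implements the switchboard traversal: ascend from the receiver's record
#' through its base-list holder(s) to the switchboard concepts, then descend
#' through the donor's declared base list to the donor records, and classify
#' the outcome:
#'
#' * `PM` perfect match: one donor name, same string, same occurrence and
#'   same interpretation.
#' * `CM` compatible match: one donor name covering the request under a
#'   different nomenclature or a different authority's reading.
#' * `MM` multiple match: the donor separates the request into two or more
#'   names; all are returned (sorted).
#' * `CM+` the donor lumps the requested concept with others; its data are
#'   combinable only together with the receiver's sibling taxa, listed in
#'   `required_receiver_siblings`.
#' * `Zero` the concept is absent from the donor's monitored range (a valid
#'   biological answer, distinct from a lookup error for a name that is not
#'   on the receiver's checklist).
#'
#' The receiver side uses the name's interpretation set (what the program
#' means by the name under its authority), the donor side its occurrence
#' sets (what each donor name actually monitors); the two differ whenever an
#' authority files several field-separable taxa under one name, which is why
#' requests are not guaranteed to be symmetric. A donor name that lumps the
#' request together with concepts the receiver does not monitor at all is
#' unusable and contributes nothing (its data cannot be decomposed).
#'
#' @param mapping A `taxon_mapping`.
#' @param receiver Receiver program id.
#' @param name Taxon name on the receiver's checklist.
#' @param donor Donor program id.
#' @param flag_symmetry Also run the reverse request(s) and attach an
#'   asymmetry flag when the match kind differs (default `TRUE`).
#' @return One-row tibble: `receiver`, `receiver_name`, `donor`,
#'   `match_type`, `donor_names` (list), `required_receiver_siblings`
#'   (list), `flags` (list of tibbles with `kind`, `message`), `message`.
#' @examples
#' m <- celastrina_fixture()
#' translate(m, "Iowa", "Celastrina ladon", "Ohio")
#' @export
translate <- function(mapping, receiver, name, donor, flag_symmetry = TRUE) {
  idx <- mapping_index(mapping)
  translate_idx(idx, receiver, name, donor, flag_symmetry = flag_symmetry)
}

translate_idx <- function(idx, receiver, name, donor, flag_symmetry = TRUE) {
  progs <- idx$sources$source_id[idx$sources$role == "program"]
  if (!receiver %in% progs) stop("unknown receiver program '", receiver, "'", call. = FALSE)
  if (!donor %in% progs) stop("unknown donor program '", donor, "'", call. = FALSE)
  key <- lookup_canon(idx, receiver, name)
  if (is.null(idx$occ[[receiver]][[key]])) {
    stop("name '", name, "' is not on the ", receiver, " checklist", call. = FALSE)
  }
  display <- idx$names_raw[[receiver]][[key]]

  if (receiver == donor) {
    return(match_result(receiver, display, donor, "PM", display,
                        character(0), list(), zero = FALSE))
  }

  cls <- classify_request(idx, receiver, key, donor)
  flags <- list()

  # curated complexity notes travel with every request touching the record;
  # for a Zero outcome the donor returns no record, so the curator's warning
  # is drawn from the donor names monitoring the same species complex (an
  # "absent" verdict inside a disputed complex still deserves the caveat)
  donor_note_keys <- cls$donor_keys
  if (cls$match_type == "Zero") {
    cx <- unique(stats::na.omit(idx$complexes[idx$occ[[receiver]][[key]]]))
    if (length(cx) > 0) {
      in_cx <- vapply(idx$occ[[donor]], function(z)
        any(idx$complexes[z] %in% cx), logical(1))
      donor_note_keys <- names(idx$occ[[donor]])[in_cx]
    }
  }
  note_texts <- unique(c(
    idx$notes[[receiver]][[key]],
    unlist(idx$notes[[donor]][donor_note_keys])
  ))
  note_texts <- note_texts[nzchar(note_texts)]
  for (t in note_texts) flags <- c(flags, list(c("complexity", t)))

  if (cls$match_type == "MM") {
    flags <- c(flags, list(c("complexity",
      "donor separates this request into several taxa; assess compatibility before combining")))
  }
  if (cls$match_type == "CM+") {
    flags <- c(flags, list(c("complexity", paste0(
      "donor lumps the requested taxon; combinable only with receiver data for ",
      paste(cls$siblings, collapse = ", ")))))
  }

  if (flag_symmetry) {
    asym <- asymmetry_flag(idx, receiver, key, donor, cls)
    if (!is.null(asym)) flags <- c(flags, list(asym))
  }

  match_result(receiver, display, donor, cls$match_type, cls$donor_names,
               cls$siblings, flags, zero = cls$match_type == "Zero")
}

# core set algebra of a request, donor-name by donor-name
classify_request <- function(idx, receiver, key, donor) {
  O_r <- idx$occ[[receiver]][[key]]
  R_eff <- idx$interp_eff[[receiver]][[key]]
  sib_occ <- idx$occ[[receiver]][setdiff(names(idx$occ[[receiver]]), key)]

  clean <- character(0)
  lumped <- character(0)
  lump_sibs <- character(0)
  skipped <- character(0)
  for (d in names(idx$occ[[donor]])) {
    O_d <- idx$occ[[donor]][[d]]
    if (length(intersect(O_d, R_eff)) == 0) next
    extra_concepts <- setdiff(O_d, R_eff)
    sibs <- names(sib_occ)[vapply(sib_occ, function(z) length(intersect(z, O_d)) > 0, logical(1))]
    if (length(extra_concepts) == 0) {
      if (length(sibs) > 0) {
        lumped <- c(lumped, d)
        lump_sibs <- unique(c(lump_sibs, sibs))
      } else {
        clean <- c(clean, d)
      }
    } else {
      uncovered <- setdiff(extra_concepts, unlist(sib_occ[sibs]))
      if (length(uncovered) > 0) {
        skipped <- c(skipped, d)  # lump extends beyond anything the receiver monitors
      } else {
        lumped <- c(lumped, d)
        lump_sibs <- unique(c(lump_sibs, sibs))
      }
    }
  }

  display_donor <- function(k) unname(idx$names_raw[[donor]][k])
  if (length(clean) >= 2) {
    keys <- sort(clean)
    list(match_type = "MM", donor_keys = keys,
         donor_names = sort(display_donor(keys)), siblings = character(0))
  } else if (length(clean) == 1) {
    d <- clean[[1]]
    same_name <- canonical_key(d) == canonical_key(key)
    same_occ <- identical(idx$occ[[donor]][[d]], O_r)
    same_interp <- identical(idx$interp_eff[[donor]][[d]], R_eff)
    type <- if (same_name && same_occ && same_interp) "PM" else "CM"
    list(match_type = type, donor_keys = d,
         donor_names = display_donor(d), siblings = character(0))
  } else if (length(lumped) > 0) {
    keys <- sort(lumped)
    sib_names <- sort(unname(vapply(lump_sibs, function(k)
      idx$names_raw[[receiver]][[k]], character(1))))
    list(match_type = "CM+", donor_keys = keys,
         donor_names = sort(display_donor(keys)), siblings = sib_names)
  } else {
    list(match_type = "Zero", donor_keys = character(0),
         donor_names = character(0), siblings = character(0),
         skipped = skipped)
  }
}

asymmetry_flag <- function(idx, receiver, key, donor, cls) {
  reverse_keys <- if (cls$match_type == "Zero") cls$skipped else cls$donor_keys
  if (length(reverse_keys) == 0) return(NULL)
  for (d in reverse_keys) {
    rev_cls <- classify_request(idx, donor, d, receiver)
    if (rev_cls$match_type != cls$match_type) {
      return(c("asymmetry", paste0(
        "reverse request (", donor, " '", idx$names_raw[[donor]][[d]],
        "' from ", receiver, ") is ", rev_cls$match_type,
        ", not ", cls$match_type)))
    }
  }
  NULL
}

match_result <- function(receiver, receiver_name, donor, match_type,
                         donor_names, siblings, flags, zero) {
  flag_tbl <- if (length(flags) == 0) {
    tibble::tibble(kind = character(0), message = character(0))
  } else {
    tibble::tibble(kind = vapply(flags, `[[`, character(1), 1),
                   message = vapply(flags, `[[`, character(1), 2))
  }
  tibble::tibble(
    receiver = receiver,
    receiver_name = receiver_name,
    donor = donor,
    match_type = match_type,
    donor_names = list(donor_names),
    required_receiver_siblings = list(siblings),
    flags = list(flag_tbl),
    message = if (zero) zero_message else NA_character_
  )
}

#' Check whether a request is symmetric
#'
#' Runs the forward request without symmetry flagging, then the reverse
#' request for each returned donor name, and reports an asymmetry flag when
#' any reverse match differs in kind from the forward one.
#'
#' @inheritParams translate
#' @return A one-row tibble (`kind`, `message`) or a zero-row tibble when
#'   the request is symmetric.
#' @export
check_symmetry <- function(mapping, receiver, name, donor) {
  idx <- mapping_index(mapping)
  key <- lookup_canon(idx, receiver, name)
  cls <- classify_request(idx, receiver, key, donor)
  f <- asymmetry_flag(idx, receiver, key, donor, cls)
  if (is.null(f)) {
    tibble::tibble(kind = character(0), message = character(0))
  } else {
    tibble::tibble(kind = f[[1]], message = f[[2]])
  }
}

#' Serialize a match result as JSON
#'
#' @param result One-row tibble from [translate()].
#' @return A JSON string.
#' @export
match_json <- function(result) {
  stopifnot(nrow(result) == 1)
  payload <- list(
    receiver = result$receiver,
    receiver_name = result$receiver_name,
    donor = result$donor,
    match_type = result$match_type,
    donor_names = result$donor_names[[1]],
    required_receiver_siblings = result$required_receiver_siblings[[1]],
    flags = result$flags[[1]]
  )
  if (!is.na(result$message)) payload$message <- result$message
  jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE)
}
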
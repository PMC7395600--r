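dwc_cols <- c(
  taxon_id = "taxonID",
  parent_id = "parentNameUsageID",
  name = "scientificName",
  rank = "taxonRank",
  source = "datasetName",
  note = "conceptNote"
)

#' Read a Darwin-Core style mapping file
#'
#' The mapping file is a single UTF-8 CSV holding every checklist (programs,
#' base authorities, and the switchboard), distinguished by the
#' `datasetName` column. Required columns are the Darwin Core Taxon terms
#' `taxonID`, `parentNameUsageID`, `scientificName`, `taxonRank`,
#' `datasetName`, plus the non-standard free-text column `conceptNote`.
#' Switchboard rows have an empty `parentNameUsageID`.
#'
#' Two structured clauses are recognized inside `conceptNote`:
#' `scope=<label>|<label>|...` declares a curated circumscription for a
#' program name whose interpretation cannot be derived from its base list,
#' and `flag: <text>` attaches a curated complexity warning that the
#' translator propagates to every request touching the record.
#'
#' @param path CSV file path.
#' @return A validated [new_mapping()] object. An empty file (header only)
#'   returns a zero-record mapping with a warning.
#' @export
read_mapping_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(dwc_cols), names(raw))
  if (length(missing) > 0) {
    stop("mapping file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rec <- tibble::tibble(
    taxon_id = raw[[dwc_cols[["taxon_id"]]]],
    parent_id = raw[[dwc_cols[["parent_id"]]]],
    source = raw[[dwc_cols[["source"]]]],
    name = raw[[dwc_cols[["name"]]]],
    rank = raw[[dwc_cols[["rank"]]]],
    note = raw[[dwc_cols[["note"]]]]
  )
  rec$parent_id[!is.na(rec$parent_id) & rec$parent_id == ""] <- NA_character_
  if (nrow(rec) == 0) {
    warning("mapping file has a header but no records", call. = FALSE)
    return(new_mapping(rec, validate = FALSE))
  }
  bad <- which(duplicated(rec$taxon_id))
  if (length(bad) > 0) {
    stop("duplicate taxonID '", rec$taxon_id[[bad[[1]]]], "' at row ",
         bad[[1]], call. = FALSE)
  }
  for (i in seq_len(nrow(rec))) {
    if (rec$source[[i]] == "switchboard") next
    ok <- tryCatch({
      parse_scientific_name(rec$name[[i]])
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop("row ", i, ": ", conditionMessage(ok), call. = FALSE)
    }
  }
  m <- new_mapping(rec, validate = FALSE)
  v <- validate_mapping(m)
  if (nrow(v) > 0) {
    stop("mapping file fails validation: ",
         paste(utils::head(v$message, 5), collapse = "; "), call. = FALSE)
  }
  m
}

#' Write a mapping back to CSV
#'
#' Inverse of [read_mapping_file()]: `read_mapping_file(write_mapping_file(m,
#' path))` is record-identical to `m`, including duplicated concept holders
#' in base lists.
#'
#' @param mapping A validated `taxon_mapping`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mapping_file <- function(mapping, path) {
  v <- validate_mapping(mapping)
  if (nrow(v) > 0) {
    stop("refusing to write an invalid mapping: ",
         paste(utils::head(v$message, 5), collapse = "; "), call. = FALSE)
  }
  out <- tibble::tibble(
    taxonID = mapping$taxon_id,
    parentNameUsageID = ifelse(is.na(mapping$parent_id), "", mapping$parent_id),
    scientificName = mapping$name,
    taxonRank = mapping$rank,
    datasetName = mapping$source,
    conceptNote = mapping$note
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a program or base checklist from CSV
#'
#' Checklist CSVs carry at least a `scientificName` column and optionally
#' `taxonRank`. Records get fresh taxon ids and unset parents: linking into
#' a base list is a later curation step.
#'
#' @param path CSV file path.
#' @param source_id Identifier for the checklist.
#' @param role `"program"` or `"base"`.
#' @param base_id Declared base authority (programs only).
#' @return A tibble of parsed records with attributes `source_id`, `role`,
#'   `base_id`. Program lists with a duplicated canonical name are rejected:
#'   program checklists are controlled vocabularies, so a duplicate is a
#'   data-entry error (base lists may duplicate names as concept holders).
#' @export
read_checklist <- function(path, source_id, role = "program", base_id = NA_character_) {
  stopifnot(role %in% c("program", "base"))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"scientificName" %in% names(raw)) {
    stop("checklist lacks a scientificName column", call. = FALSE)
  }
  parsed <- parse_scientific_name(raw$scientificName)
  canon <- canonical_string(parsed)
  if (role == "program") {
    dup <- canon[duplicated(canonical_key(canon))]
    if (length(dup) > 0) {
      stop("duplicate name in program checklist: '", dup[[1]], "'",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    taxon_id = sprintf("T%04d", seq_len(nrow(raw))),
    parent_id = NA_character_,
    name = raw$scientificName,
    rank = if ("taxonRank" %in% names(raw)) raw$taxonRank else parsed$rank,
    canon = canon
  )
  attr(out, "source_id") <- source_id
  attr(out, "role") <- role
  attr(out, "base_id") <- base_id
  out
}
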
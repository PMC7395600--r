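.celastrina_complex <- "celastrina-ladon"

#' Complex id of the built-in fixture
#'
#' @return The switchboard complex label used by [celastrina_fixture()].
#' @export
celastrina_complex_id <- function() .celastrina_complex

celastrina_flag_note <- paste(
  "flag: taxon concept interpretations differ across authorities",
  "in this complex; verify compatibility before combining")

#' Program roster of the Celastrina ladon fixture
#'
#' The ten Pollard-walk monitoring programs, their display abbreviations and
#' declared base authorities.
#'
#' @return Tibble with `source_id`, `abbrev`, `base_id`.
#' @export
celastrina_programs <- function() {
  tibble::tribble(
    ~source_id,     ~abbrev, ~base_id,
    "Illinois",     "IL",    "NABA",
    "Iowa",         "IA",    "NABA",
    "Michigan",     "MI",    "NABA",
    "Ohio",         "OH",    "NABA",
    "Tennessee",    "TN",    "NABA",
    "Florida",      "FL",    "OW",
    "Cascades",     "CAS",   "Pelham",
    "MPG",          "MPG",   "Pelham",
    "Colorado",     "CO",    "OW",
    "OrangeCounty", "OC",    "OW"
  )
}

#' The Celastrina ladon complex mapping fixture
#'
#' The curated in-code encoding of the azure-blue butterfly complex, the
#' hardest concept-resolution case in the ten-program network. Seven
#' fine-grained concepts sit on the switchboard (ladon, neglecta, lucia,
#' echo, humulus, serotina, idella; the last two fall outside every
#' program's range and are monitored by no one). Three base authorities
#' treat them differently: the broad-species authority (NABA) files all
#' seven under the single name *Celastrina ladon* — encoded as seven
#' duplicated holders sharing that name — while the splitting authorities
#' (Opler & Warren, here `OW`, without *serotina*; Pelham, all seven) carry
#' one holder per species. Ten program checklists link into their declared
#' bases exactly as curated: the lumping programs (Illinois, Michigan,
#' Tennessee with *C. ladon/neglecta*; Iowa with a broad *C. ladon*) carry
#' one record per monitored concept, Ohio and Florida split *ladon* /
#' *neglecta*, Cascades monitors *lucia* and *echo*, MPG Ranch *echo*,
#' Colorado *ladon* and *humulus*, and Orange County uses the trinomial
#' *C. ladon echo* whose curated circumscription (`scope=`) spans ladon,
#' lucia and echo.
#'
#' @return A validated `taxon_mapping`.
#' @export
celastrina_fixture <- function() {
  concepts <- c("ladon", "neglecta", "lucia", "echo", "humulus",
                "serotina", "idella")
  rows <- list()
  id_n <- 0L
  nid <- function() {
    id_n <<- id_n + 1L
    sprintf("T%04d", id_n)
  }
  add <- function(parent, source, name, rank, note = "") {
    id <- nid()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      taxon_id = id, parent_id = parent, source = source, name = name,
      rank = rank, note = note)
    id
  }

  concept_id <- character(0)
  for (cc in concepts) {
    concept_id[[cc]] <- add(NA_character_, "switchboard", cc, "concept",
                            paste0("complex=", .celastrina_complex))
  }

  # NABA files the whole complex under one broad species name: one
  # duplicated holder per concept it subsumes
  naba <- character(0)
  for (cc in concepts) {
    naba[[cc]] <- add(concept_id[[cc]], "NABA", "Celastrina ladon", "species",
                      paste0("holder for ", cc))
  }
  # Opler & Warren: full species, serotina not treated
  ow <- character(0)
  for (cc in setdiff(concepts, "serotina")) {
    ow[[cc]] <- add(concept_id[[cc]], "OW", paste("Celastrina", cc), "species")
  }
  # Pelham: all seven as full species
  pel <- character(0)
  for (cc in concepts) {
    pel[[cc]] <- add(concept_id[[cc]], "Pelham", paste("Celastrina", cc),
                     "species")
  }

  fl <- celastrina_flag_note
  # NABA-based programs
  for (p in c("Illinois", "Michigan", "Tennessee")) {
    add(naba[["ladon"]], p, "Celastrina ladon/neglecta", "conglomerate",
        paste0(fl, "; deviates from base: field-indistinguishable pair pooled"))
    add(naba[["neglecta"]], p, "Celastrina ladon/neglecta", "conglomerate", fl)
  }
  add(naba[["ladon"]], "Iowa", "Celastrina ladon", "species", fl)
  add(naba[["neglecta"]], "Iowa", "Celastrina ladon", "species", fl)
  add(naba[["ladon"]], "Ohio", "Celastrina ladon", "species",
      paste0(fl, "; deviates from base: splits the broad concept"))
  add(naba[["neglecta"]], "Ohio", "Celastrina neglecta", "species", fl)
  # O&W-based programs
  add(ow[["ladon"]], "Florida", "Celastrina ladon", "species", fl)
  add(ow[["neglecta"]], "Florida", "Celastrina neglecta", "species", fl)
  add(ow[["ladon"]], "Colorado", "Celastrina ladon", "species", fl)
  add(ow[["humulus"]], "Colorado", "Celastrina humulus", "species", fl)
  add(ow[["echo"]], "OrangeCounty", "Celastrina ladon echo", "subspecies",
      paste("scope=ladon|lucia|echo; curated circumscription of the",
            "program's trinomial usage"))
  # Pelham-based programs
  add(pel[["lucia"]], "Cascades", "Celastrina lucia", "species", fl)
  add(pel[["echo"]], "Cascades", "Celastrina echo", "species", fl)
  add(pel[["echo"]], "MPG", "Celastrina echo", "species")

  new_mapping(dplyr::bind_rows(rows))
}

#' Expected integration matrix for the Celastrina ladon complex
#'
#' The curators' pre-constructed compatibility matrix: one row per
#' (receiver program, receiver taxon), one column per donor program, every
#' off-diagonal cell giving the expected match code, used as the regression
#' surface that [build_matrix()] output is certified against. All
#' comparisons carry a warning flag except the two requests between Orange
#' County and MPG Ranch, the only pair whose taxa align one-to-one with no
#' concept dispute in either direction.
#'
#' @return An `integration_matrix` tibble.
#' @export
expected_celastrina_matrix <- function() {
  progs <- celastrina_programs()$source_id
  taxa <- list(
    c("Illinois", "Celastrina ladon/neglecta"),
    c("Iowa", "Celastrina ladon"),
    c("Michigan", "Celastrina ladon/neglecta"),
    c("Ohio", "Celastrina ladon"),
    c("Ohio", "Celastrina neglecta"),
    c("Tennessee", "Celastrina ladon/neglecta"),
    c("Florida", "Celastrina ladon"),
    c("Florida", "Celastrina neglecta"),
    c("Cascades", "Celastrina lucia"),
    c("Cascades", "Celastrina echo"),
    c("MPG", "Celastrina echo"),
    c("Colorado", "Celastrina ladon"),
    c("Colorado", "Celastrina humulus"),
    c("OrangeCounty", "Celastrina ladon echo")
  )
  # codes per row, in donor order IL IA MI OH TN FL CAS MPG CO OC
  codes <- list(
    c("X",    "CM",   "PM",   "MM",  "PM",   "MM", "MM",   "CM",   "MM",   "CM"),
    c("CM",   "X",    "CM",   "MM",  "CM",   "MM", "MM",   "CM",   "MM",   "CM"),
    c("PM",   "CM",   "X",    "MM",  "PM",   "MM", "MM",   "CM",   "MM",   "CM"),
    c("CM+",  "CM+",  "CM+",  "X",   "CM+",  "CM", "MM",   "CM",   "MM",   "CM"),
    c("CM+",  "CM+",  "CM+",  "X",   "CM+",  "PM", "Zero", "Zero", "Zero", "Zero"),
    c("PM",   "CM",   "PM",   "MM",  "X",    "MM", "MM",   "CM",   "MM",   "CM"),
    c("CM+",  "CM+",  "CM+",  "CM",  "CM+",  "X",  "Zero", "Zero", "PM",   "Zero"),
    c("CM+",  "CM+",  "CM+",  "PM",  "CM+",  "X",  "Zero", "Zero", "Zero", "Zero"),
    c("Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "X",  "Zero", "Zero", "Zero"),
    c("Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "X",  "PM",   "Zero", "CM"),
    c("Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "PM", "X",    "Zero", "CM"),
    c("Zero", "Zero", "Zero", "CM",  "Zero", "PM",  "Zero", "Zero", "X",    "Zero"),
    c("Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "Zero", "X",  "Zero"),
    c("Zero", "Zero", "Zero", "CM",  "Zero", "CM",  "MM",   "CM",   "CM",   "X")
  )
  rows <- list()
  for (i in seq_along(taxa)) {
    p <- taxa[[i]][[1]]
    tx <- taxa[[i]][[2]]
    for (j in seq_along(progs)) {
      d <- progs[[j]]
      code <- codes[[i]][[j]]
      flagged <- code != "X" &&
        !(sort(c(p, d))[1] == "MPG" && sort(c(p, d))[2] == "OrangeCounty")
      rows[[length(rows) + 1]] <- tibble::tibble(
        receiver_program = p, receiver_taxon = tx, donor_program = d,
        code = code, flagged = flagged)
    }
  }
  out <- tibble::new_tibble(dplyr::bind_rows(rows), class = "integration_matrix")
  attr(out, "complex_id") <- .celastrina_complex
  attr(out, "programs") <- progs
  out
}
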
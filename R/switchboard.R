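#' Validate the structural invariants of a mapping
#'
#' Checks, without stopping: unique taxon ids; parents that resolve; no
#' parent cycles; role chain (program record -> holder in that program's
#' declared base, base holder -> switchboard concept, switchboard roots have
#' no parent); no duplicate canonical names within a program checklist; no
#' two holders in one base list sharing both name and parent concept.
#'
#' @param mapping A `taxon_mapping`.
#' @return Tibble of violations (`taxon_id`, `kind`, `message`); zero rows
#'   when the mapping is sound.
#' @export
validate_mapping <- function(mapping) {
  out <- list()
  add <- function(taxon_id, kind, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      taxon_id = taxon_id, kind = kind, message = message)
  }
  rec <- as.data.frame(mapping, stringsAsFactors = FALSE)
  srcs <- derive_sources(mapping)
  role_of <- stats::setNames(srcs$role, srcs$source_id)
  base_of <- stats::setNames(srcs$base_id, srcs$source_id)

  dup <- rec$taxon_id[duplicated(rec$taxon_id)]
  for (d in unique(dup)) add(d, "duplicate_id", paste0("duplicate taxon id ", d))

  known <- rec$taxon_id
  source_of <- stats::setNames(rec$source, rec$taxon_id)
  parent_of <- stats::setNames(rec$parent_id, rec$taxon_id)

  for (i in seq_len(nrow(rec))) {
    id <- rec$taxon_id[[i]]
    src <- rec$source[[i]]
    pid <- rec$parent_id[[i]]
    role <- role_of[[src]]
    if (role == "switchboard") {
      if (!is.na(pid)) add(id, "switchboard_parent",
                          paste0("switchboard record ", id, " has a parent"))
      next
    }
    if (is.na(pid)) {
      add(id, "dangling_parent", paste0(src, " record ", id, " has no parent"))
      next
    }
    if (!pid %in% known) {
      add(id, "dangling_parent",
          paste0(src, " record ", id, " points at missing parent ", pid))
      next
    }
    psrc <- source_of[[pid]]
    if (role == "base" && psrc != "switchboard") {
      add(id, "cross_role",
          paste0("base record ", id, " must parent into the switchboard, not ", psrc))
    }
    if (role == "program") {
      declared <- base_of[[src]]
      if (is.na(declared)) {
        add(id, "cross_role",
            paste0("program ", src, " links into more than one base list"))
      } else if (psrc != declared) {
        add(id, "cross_role",
            paste0("program ", src, " record ", id, " parents into ", psrc,
                   " instead of its declared base ", declared))
      }
    }
  }

  # cycles
  for (id in rec$taxon_id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur) && cur %in% known) {
      if (cur %in% seen) {
        if (cur == id) add(id, "cycle", paste0("parent cycle through ", id))
        break
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }

  # program-list name uniqueness
  for (s in srcs$source_id[srcs$role == "program"]) {
    sub <- rec[rec$source == s, ]
    d <- sub$canon[duplicated(sub$canon) & !duplicated(sub[c("canon", "parent_id")])]
    # duplicates of the same name are legitimate only as links to distinct
    # holders (multi-concept names); identical (name, parent) pairs are not
    dd <- sub[duplicated(sub[c("canon", "parent_id")]), ]
    for (j in seq_len(nrow(dd))) {
      add(dd$taxon_id[[j]], "duplicate_name",
          paste0("program ", s, " repeats name '", dd$name[[j]],
                 "' with the same parent"))
    }
  }

  # duplicated holders must hang from distinct concepts
  for (s in srcs$source_id[srcs$role == "base"]) {
    sub <- rec[rec$source == s, ]
    dd <- sub[duplicated(sub[c("canon", "parent_id")]), ]
    for (j in seq_len(nrow(dd))) {
      add(dd$taxon_id[[j]], "duplicate_holder",
          paste0("base ", s, " repeats holder '", dd$name[[j]],
                 "' under the same concept"))
    }
  }

  if (length(out) == 0) {
    tibble::tibble(taxon_id = character(0), kind = character(0),
                   message = character(0))
  } else {
    dplyr::bind_rows(out)
  }
}

#' Switchboard concepts monitored under a name
#'
#' Upward closure: all switchboard concept nodes reachable by following
#' parent links from every record bearing `name` in checklist `source_id`.
#' For a program this is the record's occurrence set: the concepts the
#' program actually monitors under that name within its range (a program
#' lumping two taxa under one name has two same-named records, one per
#' holder).
#'
#' @param mapping A `taxon_mapping`.
#' @param source_id Checklist identifier.
#' @param name Taxon name (any spelling-normalized form).
#' @return Tibble of concept nodes: `concept_id`, `label`, `complex_id`.
#' @export
concepts_of <- function(mapping, source_id, name) {
  idx <- mapping_index(mapping)
  concepts_of_idx(idx, source_id, name)
}

concepts_of_idx <- function(idx, source_id, name) {
  if (!source_id %in% idx$sources$source_id) {
    stop("unknown source '", source_id, "'", call. = FALSE)
  }
  key <- lookup_canon(idx, source_id, name)
  ids <- idx$occ[[source_id]][[key]]
  if (is.null(ids)) {
    stop("name '", name, "' is not on the ", source_id, " checklist",
         call. = FALSE)
  }
  tibble::tibble(
    concept_id = ids,
    label = unname(idx$labels[ids]),
    complex_id = unname(idx$complexes[ids])
  )
}

lookup_canon <- function(idx, source_id, name) {
  keys <- names(idx$occ[[source_id]])
  key <- canonical_key(name)
  if (key %in% canonical_key(keys)) {
    return(keys[match(key, canonical_key(keys))])
  }
  # tolerate raw strings with stray whitespace or case differences
  parsed <- tryCatch(canonical_string(parse_scientific_name(name)),
                     error = function(e) name)
  hit <- match(canonical_key(parsed), canonical_key(keys))
  if (is.na(hit)) parsed else keys[[hit]]
}

#' Interpretation set of a program name
#'
#' The circumscription of a checklist name under the program's own reading:
#' the closure over all holders in the program's base list that share the
#' name (so a NABA-style broad "Celastrina ladon" expands to every concept
#' the authority files under that name), a curated `scope=` override when
#' the base list cannot express the program's deviation, always including
#' the record's own occurrence set. This is the set the program *means*
#' when it requests data as a receiver; the occurrence set
#' ([concepts_of()]) is what it can *supply* as a donor.
#'
#' @inheritParams concepts_of
#' @return Tibble of concept nodes as in [concepts_of()].
#' @export
interpretation_of <- function(mapping, source_id, name) {
  idx <- mapping_index(mapping)
  key <- lookup_canon(idx, source_id, name)
  ids <- idx$interp[[source_id]][[key]]
  if (is.null(ids)) {
    stop("name '", name, "' is not on the ", source_id, " checklist",
         call. = FALSE)
  }
  tibble::tibble(
    concept_id = ids,
    label = unname(idx$labels[ids]),
    complex_id = unname(idx$complexes[ids])
  )
}

#' Add a duplicated concept holder to a base list
#'
#' Inserts a new base-list record with the given name whose parent is the
#' given switchboard concept. Duplicate name strings across holders are the
#' mechanism that preserves program granularity; re-adding an existing
#' (name, concept) holder is refused.
#'
#' @param mapping A `taxon_mapping`.
#' @param base_id Base checklist to extend.
#' @param name Holder name string.
#' @param concept_id Switchboard concept id the holder represents.
#' @param note Optional conceptNote text.
#' @return The extended mapping.
#' @export
add_holder <- function(mapping, base_id, name, concept_id, note = "") {
  srcs <- mapping_sources(mapping)
  if (!base_id %in% srcs$source_id[srcs$role == "base"]) {
    stop("'", base_id, "' is not a base list", call. = FALSE)
  }
  sb <- mapping$taxon_id[mapping$source == "switchboard"]
  if (!concept_id %in% sb) {
    stop("unknown switchboard concept '", concept_id, "'", call. = FALSE)
  }
  canon <- canonical_string(parse_scientific_name(name))
  clash <- mapping$source == base_id & mapping$canon == canon &
    !is.na(mapping$parent_id) & mapping$parent_id == concept_id
  if (any(clash)) {
    stop("holder ('", name, "', ", concept_id, ") already present in ",
         base_id, call. = FALSE)
  }
  row <- tibble::tibble(
    taxon_id = next_taxon_id(mapping), parent_id = concept_id,
    source = base_id, name = name, rank = "species", note = note,
    canon = canon
  )
  out <- dplyr::bind_rows(tibble::as_tibble(mapping), row)
  new_mapping(out[, c("taxon_id", "parent_id", "source", "name", "rank", "note")],
              validate = FALSE)
}
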
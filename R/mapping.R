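#' Construct a taxon mapping from Darwin-Core style records
#'
#' The mapping is the package's central data structure: a single table of
#' taxon records in which every monitoring-program name is the child of a
#' holder record in that program's declared base authority list, and every
#' base holder is the child of a fine-grained concept node on the master
#' "switchboard" list. A base list may carry several holders with the same
#' name string (duplicated holders), one per concept it subsumes under that
#' name; this is what preserves program-level granularity when authorities
#' lump taxa.
#'
#' @param records A data frame with columns `taxon_id`, `parent_id`
#'   (`NA` for switchboard rows), `source`, `name`, `rank` and optionally
#'   `note`. The source `"switchboard"` is reserved for concept nodes.
#' @param validate Check structural invariants and stop on violations.
#' @return A tibble of class `taxon_mapping` with a `sources` attribute
#'   (tibble of `source_id`, `role`, `base_id`).
#' @seealso [read_mapping_file()], [validate_mapping()]
#' @export
new_mapping <- function(records, validate = TRUE) {
  records <- tibble::as_tibble(records)
  required <- c("taxon_id", "parent_id", "source", "name", "rank")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("mapping records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"note" %in% names(records)) records$note <- ""
  records$note[is.na(records$note)] <- ""
  records <- records[, c(required, "note")]
  records$canon <- ifelse(
    records$source == "switchboard",
    canonical_key(records$name),
    canonical_string(parse_scientific_name(records$name))
  )
  m <- tibble::new_tibble(records, class = "taxon_mapping")
  attr(m, "sources") <- derive_sources(m)
  if (validate) {
    v <- validate_mapping(m)
    if (nrow(v) > 0) {
      stop("invalid mapping: ", paste(v$message, collapse = "; "),
           call. = FALSE)
    }
    attr(m, "index") <- build_mapping_index(m)
  }
  m
}

derive_sources <- function(m) {
  by_id <- stats::setNames(m$source, m$taxon_id)
  parent_source <- function(src) {
    pids <- m$parent_id[m$source == src]
    pids <- pids[!is.na(pids)]
    unique(by_id[pids[pids %in% names(by_id)]])
  }
  src <- unique(m$source)
  role <- character(length(src))
  base <- rep(NA_character_, length(src))
  for (i in seq_along(src)) {
    if (src[[i]] == "switchboard") {
      role[[i]] <- "switchboard"
      next
    }
    ps <- parent_source(src[[i]])
    if (length(ps) == 0) {
      # no resolvable parents: treat as base only if parents are absent ids
      role[[i]] <- "base"
    } else if (identical(ps, "switchboard")) {
      role[[i]] <- "base"
    } else {
      role[[i]] <- "program"
      base[[i]] <- if (length(setdiff(ps, "switchboard")) == 1) {
        setdiff(ps, "switchboard")
      } else {
        NA_character_  # flagged by validate_mapping
      }
    }
  }
  tibble::tibble(source_id = src, role = role, base_id = base)
}

#' @export
print.taxon_mapping <- function(x, ...) {
  s <- mapping_sources(x)
  cat("<taxon_mapping> ", nrow(x), " records; ",
      sum(s$role == "program"), " program, ",
      sum(s$role == "base"), " base, ",
      sum(s$role == "switchboard"), " switchboard checklist(s)\n", sep = "")
  NextMethod()
}

#' Source roster of a mapping
#'
#' @param mapping A `taxon_mapping`.
#' @return Tibble with `source_id`, `role` (program/base/switchboard) and
#'   `base_id` (programs only: the declared base authority).
#' @export
mapping_sources <- function(mapping) {
  attr(mapping, "sources") %||% derive_sources(mapping)
}

#' Extract one checklist from a mapping
#'
#' @param mapping A `taxon_mapping`.
#' @param source_id Checklist identifier (program, base, or "switchboard").
#' @return Tibble of that source's records, row order preserved.
#' @export
mapping_checklist <- function(mapping, source_id) {
  if (!source_id %in% mapping$source) {
    stop("unknown source '", source_id, "'", call. = FALSE)
  }
  out <- tibble::as_tibble(mapping)[mapping$source == source_id, ]
  s <- mapping_sources(mapping)
  k <- match(source_id, s$source_id)
  attr(out, "source_id") <- source_id
  attr(out, "role") <- s$role[[k]]
  attr(out, "base_id") <- s$base_id[[k]]
  out
}

next_taxon_id <- function(mapping) {
  nums <- suppressWarnings(as.integer(sub("^T", "", mapping$taxon_id)))
  sprintf("T%04d", max(c(0L, nums), na.rm = TRUE) + 1L)
}

# note-field conventions: "scope=a|b|c" carries a curated interpretation
# override; a "flag:" clause carries a curated complexity warning.
note_scope <- function(note) {
  hit <- stringr::str_match(note, "scope=([A-Za-z|._-]+)")[, 2]
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) return(NULL)
  unique(unlist(strsplit(hit, "|", fixed = TRUE)))
}

note_flag <- function(note) {
  hit <- stringr::str_match(note, "flag:\\s*([^;]*)")[, 2]
  trimws(hit[!is.na(hit)])
}

# ---- fast lookup index --------------------------------------------------
#
# translate()/build_matrix() are called hundreds of times per matrix; all
# per-name set computations are done once here.

mapping_index <- function(mapping) {
  attr(mapping, "index") %||% build_mapping_index(mapping)
}

build_mapping_index <- function(mapping) {
  stopifnot(inherits(mapping, "taxon_mapping"))
  srcs <- mapping_sources(mapping)
  rec <- as.data.frame(mapping, stringsAsFactors = FALSE)

  # switchboard concept of every record: propagate down the (acyclic,
  # depth <= 2) parent chain by repeated parent lookup
  conc <- ifelse(rec$source == "switchboard", rec$taxon_id, NA_character_)
  for (hop in 1:4) {
    todo <- which(is.na(conc))
    if (length(todo) == 0) break
    up <- match(rec$parent_id[todo], rec$taxon_id)
    resolved <- !is.na(up) & !is.na(conc[up])
    conc[todo[resolved]] <- conc[up[resolved]]
    if (!any(resolved)) break
  }
  rec$concept <- conc

  sb <- rec[rec$source == "switchboard", ]
  labels <- stats::setNames(sb$canon, sb$taxon_id)
  complexes <- stats::setNames(
    stringr::str_match(sb$note, "complex=([A-Za-z0-9._-]+)")[, 2],
    sb$taxon_id
  )

  occ <- list()      # occ[[source]][[canon]] = sorted concept ids
  notes <- list()    # curated flag texts per (source, canon)
  scopes <- list()   # curated interpretation override per (source, canon)
  names_raw <- list()
  for (s in srcs$source_id) {
    sub <- rec[rec$source == s, ]
    occ[[s]] <- lapply(split(sub$concept, sub$canon),
                       function(z) sort(unique(z[!is.na(z)])))
    notes[[s]] <- lapply(split(sub$note, sub$canon),
                         function(z) unique(unlist(lapply(z, note_flag))))
    scopes[[s]] <- lapply(split(sub$note, sub$canon),
                          function(z) note_scope(paste(z, collapse = "; ")))
    names_raw[[s]] <- vapply(split(sub$name, sub$canon), `[[`, character(1), 1)
  }

  label_to_id <- stats::setNames(names(labels), unname(labels))

  # interpretation set of each program name: the circumscription of the name
  # under the program's base authority (closure over same-named base
  # holders), optionally overridden by a curated scope, always including the
  # record's own occurrence set.
  interp <- list()
  interp_eff <- list()
  for (i in seq_len(nrow(srcs))) {
    s <- srcs$source_id[[i]]
    if (srcs$role[[i]] != "program") next
    b <- srcs$base_id[[i]]
    base_occ <- occ[[b]] %||% list()
    names(base_occ) <- canonical_key(names(base_occ))
    closure <- function(canon_name) base_occ[[canonical_key(canon_name)]] %||% character(0)
    interp[[s]] <- list()
    prog_names <- names(occ[[s]])
    parsed <- parse_scientific_name(unname(names_raw[[s]][prog_names]))
    for (ni in seq_along(prog_names)) {
      n <- prog_names[[ni]]
      own <- occ[[s]][[n]]
      sc <- scopes[[s]][[n]]
      if (!is.null(sc)) {
        ids <- unname(label_to_id[sc])
        set <- sort(unique(c(ids[!is.na(ids)], own)))
      } else {
        set <- switch(
          parsed$rank[[ni]],
          conglomerate = sort(unique(unlist(lapply(
            parsed$conglomerate[[ni]],
            function(e) closure(paste(parsed$genus[[ni]], e)))))),
          subspecies = {
            full <- closure(n)
            if (length(full) > 0) full else {
              closure(paste(parsed$genus[[ni]], parsed$epithet[[ni]]))
            }
          },
          closure(n)
        )
        set <- sort(unique(c(set, own)))
      }
      interp[[s]][[n]] <- set
    }
    # effective scope: a name does not claim concepts that sibling names on
    # the same checklist monitor in their own right
    interp_eff[[s]] <- list()
    for (n in names(interp[[s]])) {
      others <- unlist(occ[[s]][setdiff(names(occ[[s]]), n)])
      interp_eff[[s]][[n]] <-
        sort(unique(c(setdiff(interp[[s]][[n]], others), occ[[s]][[n]])))
    }
  }

  list(
    sources = srcs, records = rec,
    labels = labels, label_to_id = label_to_id, complexes = complexes,
    occ = occ, notes = notes, scopes = scopes, names_raw = names_raw,
    interp = interp, interp_eff = interp_eff
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
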
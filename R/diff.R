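#' Read a curation table
#'
#' Curator-supplied resolutions for name pairs that heuristics cannot
#' classify (chiefly deliberate synonym substitutions). Columns:
#' `leftSource`, `leftName`, `rightSource`, `rightName`, `dtype`
#' (`F|G|S|L|C|U`), `sSubtype`
#' (`promotion|misdetermination|synonym|subspecies_use`, S only), `note`.
#'
#' @param path CSV path.
#' @return A validated curation tibble.
#' @export
read_curation_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("leftSource", "leftName", "rightSource", "rightName", "dtype",
            "sSubtype", "note")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("curation table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_curation(raw)
}

#' Assemble a curation table in code
#'
#' @param left,right Name strings of the curated pair.
#' @param dtype Discrepancy codes.
#' @param s_subtype Optional S subtype.
#' @param note Free text.
#' @return A curation tibble.
#' @export
curation_table <- function(left, right, dtype, s_subtype = NA_character_,
                           note = "") {
  validate_curation(tibble::tibble(
    leftSource = NA_character_, leftName = left,
    rightSource = NA_character_, rightName = right,
    dtype = dtype, sSubtype = s_subtype, note = note
  ))
}

validate_curation <- function(cur) {
  key <- paste(canonical_key(cur$leftName), canonical_key(cur$rightName),
               sep = "\r")
  split_types <- split(cur$dtype, key)
  bad <- names(split_types)[vapply(split_types, function(z)
    length(unique(z)) > 1, logical(1))]
  if (length(bad) > 0) {
    stop("contradictory curation entries for pair: ",
         gsub("\r", " / ", bad[[1]]), call. = FALSE)
  }
  tibble::as_tibble(cur)
}

as_diff_checklist <- function(x, source_id = "list") {
  if (is.character(x)) {
    x <- tibble::tibble(name = x)
  } else {
    x <- tibble::as_tibble(x)
    if (!"name" %in% names(x)) {
      stop("checklist needs a 'name' column", call. = FALSE)
    }
  }
  sid <- attr(x, "source_id") %||% source_id
  # alignment is over name lists: a name linked to several concept holders
  # appears in the mapping once per link but is one checklist entry
  x <- x[!duplicated(canonical_key(x$name)), , drop = FALSE]
  parsed <- parse_scientific_name(x$name)
  out <- tibble::tibble(
    name = x$name,
    canon = canonical_string(parsed),
    genus = parsed$genus,
    epithet = parsed$epithet,
    infraspecific = parsed$infraspecific,
    conglomerate = parsed$conglomerate,
    rank = parsed$rank,
    subfamily = if ("subfamily" %in% names(x)) x$subfamily else NA_character_
  )
  attr(out, "source_id") <- sid
  out
}

#' Align two checklists and classify their discrepancies
#'
#' Pairs are formed in priority order: (1) exact canonical-name matches,
#' (2) curation-table entries, (3) heuristic candidates — identical species
#' binomial with differing subspecies use; same genus with a small epithet
#' edit (spelling candidates); same epithet under a different genus; a
#' conglomerate whose component binomials match names on the other side;
#' a one-to-one leftover pair within a genus (proposed as an unresolved
#' species-level deviation: only a curator can certify a synonymy).
#' Everything left is unmatched. When one name has several equally good
#' candidates the name is reported as ambiguous and left unmatched, never
#' silently paired.
#'
#' @param a,b Checklists: tibbles with a `name` column (e.g. from
#'   [read_checklist()]) or plain character vectors.
#' @param curation Optional curation tibble ([read_curation_table()]).
#' @return Object of class `checklist_alignment`: list with `pairs` (one
#'   row per left/right link: `left_name`, `right_name`, `dtype`,
#'   `s_subtype`, `note`, `pair_id`), `unmatched_left`, `unmatched_right`,
#'   `ambiguous`, and the inputs' sizes.
#' @export
align_checklists <- function(a, b, curation = NULL) {
  a <- as_diff_checklist(a, "left")
  b <- as_diff_checklist(b, "right")
  left <- a
  right <- b
  left$used <- FALSE
  right$used <- FALSE
  pairs <- list()
  ambiguous <- list()
  pair_n <- 0L
  add_pair <- function(li, ri, dtype, s_subtype = NA_character_, note = "") {
    pair_n <<- pair_n + 1L
    for (k in seq_along(ri)) {
      pairs[[length(pairs) + 1]] <<- tibble::tibble(
        pair_id = pair_n,
        left_name = left$name[[li]], right_name = right$name[[ri[[k]]]],
        dtype = list(dtype), s_subtype = s_subtype, note = note)
    }
    left$used[li] <<- TRUE
    right$used[ri] <<- TRUE
  }

  # (1) exact canonical matches
  for (i in seq_len(nrow(left))) {
    j <- which(!right$used & canonical_key(right$canon) == canonical_key(left$canon[[i]]))
    if (length(j) > 0) add_pair(i, j[[1]], character(0))
  }

  # (2) curated pairs; entries addressed to other checklists (explicit
  # sources that match neither side) are not this alignment's business
  if (!is.null(curation)) {
    curation <- validate_curation(curation)
    here <- c(attr(a, "source_id"), attr(b, "source_id"))
    keep <- (is.na(curation$leftSource) | curation$leftSource %in% here) &
      (is.na(curation$rightSource) | curation$rightSource %in% here)
    curation <- curation[keep, ]
    for (k in seq_len(nrow(curation))) {
      lkey <- canonical_key(curation$leftName[[k]])
      rkey <- canonical_key(curation$rightName[[k]])
      on_left <- lkey %in% canonical_key(left$canon)
      on_right <- rkey %in% canonical_key(right$canon)
      if (!on_left && !on_right) {
        stop("curation entry references names absent from both lists: '",
             curation$leftName[[k]], "' / '", curation$rightName[[k]], "'",
             call. = FALSE)
      }
      i <- which(!left$used & canonical_key(left$canon) == lkey)
      j <- which(!right$used & canonical_key(right$canon) == rkey)
      if (length(i) > 0 && length(j) > 0) {
        add_pair(i[[1]], j[[1]], curation$dtype[[k]],
                 curation$sSubtype[[k]],
                 if (is.na(curation$note[[k]])) "curated" else curation$note[[k]])
      }
    }
  }

  # (3a) conglomerates vs their split components
  for (i in which(!left$used & left$rank == "conglomerate")) {
    comp <- paste(left$genus[[i]], left$conglomerate[[i]])
    j <- which(!right$used & canonical_key(right$canon) %in% canonical_key(comp))
    if (length(j) >= 1) add_pair(i, j, "C", note = "conglomerate pooling")
  }
  for (j in which(!right$used & right$rank == "conglomerate")) {
    comp <- paste(right$genus[[j]], right$conglomerate[[j]])
    i <- which(!left$used & canonical_key(left$canon) %in% canonical_key(comp))
    if (length(i) >= 1) {
      # one right conglomerate consumes several left components
      pair_n <- pair_n + 1L
      for (ii in i) {
        pairs[[length(pairs) + 1]] <- tibble::tibble(
          pair_id = pair_n, left_name = left$name[[ii]],
          right_name = right$name[[j]], dtype = list("C"),
          s_subtype = NA_character_, note = "conglomerate pooling")
      }
      left$used[i] <- TRUE
      right$used[j] <- TRUE
    }
  }

  # (3b) same species binomial, different subspecies use
  for (i in which(!left$used & left$rank %in% c("species", "subspecies"))) {
    bi <- paste(left$genus[[i]], left$epithet[[i]])
    j <- which(!right$used & right$rank %in% c("species", "subspecies") &
                 canonical_key(paste(right$genus, right$epithet)) == canonical_key(bi) &
                 canonical_key(right$infraspecific) != canonical_key(left$infraspecific[[i]]))
    if (length(j) == 1) {
      add_pair(i, j, "S", "subspecies_use", "rank-use deviation")
    } else if (length(j) > 1) {
      ambiguous[[length(ambiguous) + 1]] <- tibble::tibble(
        name = left$name[[i]], candidates = list(right$name[j]))
    }
  }

  # (3c) spelling candidates: same genus, small epithet edit, same prefix
  for (i in which(!left$used & left$rank == "species")) {
    j <- which(!right$used & right$rank == "species" &
                 right$genus == left$genus[[i]])
    if (length(j) == 0) next
    d <- epithet_distance(left$epithet[[i]], right$epithet[j])
    ok <- d <= 2 & substr(right$epithet[j], 1, 2) == substr(left$epithet[[i]], 1, 2)
    j <- j[ok]
    d <- d[ok]
    if (length(j) == 0) next
    best <- j[d == min(d)]
    if (length(best) == 1) {
      add_pair(i, best, "L", note = "spelling variant")
    } else {
      ambiguous[[length(ambiguous) + 1]] <- tibble::tibble(
        name = left$name[[i]], candidates = list(right$name[best]))
    }
  }

  # (3d) same epithet, different genus
  for (i in which(!left$used & left$rank == "species")) {
    j <- which(!right$used & right$rank == "species" &
                 right$epithet == left$epithet[[i]] &
                 right$genus != left$genus[[i]])
    if (length(j) == 1) {
      add_pair(i, j, "G", note = "genus deviation")
    } else if (length(j) > 1) {
      ambiguous[[length(ambiguous) + 1]] <- tibble::tibble(
        name = left$name[[i]], candidates = list(right$name[j]))
    }
  }

  # (3e) one-to-one leftovers within a genus: unresolved species deviation
  for (g in unique(left$genus[!left$used])) {
    i <- which(!left$used & left$genus == g & left$rank == "species")
    j <- which(!right$used & right$genus == g & right$rank == "species")
    if (length(i) == 1 && length(j) == 1) {
      add_pair(i, j, "S", NA_character_, "unresolved")
    }
  }

  pairs_tbl <- if (length(pairs) == 0) {
    tibble::tibble(pair_id = integer(0), left_name = character(0),
                   right_name = character(0), dtype = list(),
                   s_subtype = character(0), note = character(0))
  } else {
    dplyr::bind_rows(pairs)
  }
  structure(list(
    pairs = pairs_tbl,
    unmatched_left = left$name[!left$used],
    unmatched_right = right$name[!right$used],
    ambiguous = if (length(ambiguous) == 0) {
      tibble::tibble(name = character(0), candidates = list())
    } else {
      dplyr::bind_rows(ambiguous)
    },
    n_left = nrow(left), n_right = nrow(right),
    left_source = attr(a, "source_id"), right_source = attr(b, "source_id"),
    curation = curation
  ), class = "checklist_alignment")
}

#' @export
print.checklist_alignment <- function(x, ...) {
  cat("<checklist_alignment> ", length(unique(x$pairs$pair_id)), " pairs, ",
      length(x$unmatched_left), " + ", length(x$unmatched_right),
      " unmatched\n", sep = "")
  invisible(x)
}

#' Classify one aligned name pair
#'
#' Returns every applicable discrepancy code for a matched pair (or a
#' one-sided record): `G` genus deviation, `S` species-epithet deviation
#' (subtyped when a curation entry or rank structure supplies the reason),
#' `L` spelling variant, `C` conglomerate, `U` unmatched. Exact matches
#' return zero rows; a pair may carry several codes at once.
#'
#' @param left,right Character vectors of names (either may be empty /
#'   `NULL` for a one-sided record; conglomerate comparisons pass several
#'   names on the split side).
#' @param curation Optional curation tibble consulted before heuristics.
#' @return Tibble with columns `code`, `s_subtype`, `note`.
#' @export
classify_pair <- function(left, right, curation = NULL) {
  left <- left[!is.na(left) & nzchar(left)]
  right <- right[!is.na(right) & nzchar(right)]
  if (length(left) == 0 && length(right) == 0) {
    stop("classify_pair needs at least one side", call. = FALSE)
  }
  out <- function(code, s_subtype = NA_character_, note = "") {
    tibble::tibble(code = code, s_subtype = s_subtype, note = note)
  }
  if (length(left) == 0 || length(right) == 0) return(out("U"))

  if (!is.null(curation)) {
    curation <- validate_curation(curation)
    hit <- canonical_key(curation$leftName) %in% canonical_key(left) &
      canonical_key(curation$rightName) %in% canonical_key(right)
    rev_hit <- canonical_key(curation$rightName) %in% canonical_key(left) &
      canonical_key(curation$leftName) %in% canonical_key(right)
    k <- which(hit | rev_hit)
    if (length(k) > 0) {
      return(out(curation$dtype[[k[[1]]]], curation$sSubtype[[k[[1]]]],
                 "curated"))
    }
  }

  pl <- parse_scientific_name(left)
  pr <- parse_scientific_name(right)

  # conglomerate against its components (either orientation)
  congl_vs <- function(pc, ps) {
    comp <- canonical_key(paste(pc$genus[[1]], pc$conglomerate[[1]]))
    length(ps$genus) >= 1 &&
      all(canonical_key(canonical_string(ps)) %in% comp)
  }
  if (nrow(pl) == 1 && pl$rank[[1]] == "conglomerate" && congl_vs(pl, pr)) {
    return(out("C"))
  }
  if (nrow(pr) == 1 && pr$rank[[1]] == "conglomerate" && congl_vs(pr, pl)) {
    return(out("C"))
  }

  if (nrow(pl) != 1 || nrow(pr) != 1) {
    stop("multi-name comparisons are only defined for conglomerates",
         call. = FALSE)
  }
  if (canonical_key(canonical_string(pl)) == canonical_key(canonical_string(pr))) {
    return(out(character(0)))
  }
  codes <- list()
  if (pl$genus != pr$genus && pl$epithet == pr$epithet && nzchar(pl$epithet)) {
    codes[[length(codes) + 1]] <- out("G")
  }
  if (pl$genus == pr$genus && pl$epithet != pr$epithet) {
    d <- epithet_distance(pl$epithet, pr$epithet)
    if (d <= 2 && substr(pl$epithet, 1, 2) == substr(pr$epithet, 1, 2)) {
      codes[[length(codes) + 1]] <- out("L")
    } else {
      codes[[length(codes) + 1]] <- out("S", NA_character_, "unresolved")
    }
  }
  if (pl$genus != pr$genus && pl$epithet != pr$epithet &&
      nzchar(pl$epithet) && nzchar(pr$epithet)) {
    codes[[length(codes) + 1]] <- out("G")
    codes[[length(codes) + 1]] <- out("S", NA_character_, "unresolved")
  }
  if (pl$genus == pr$genus && pl$epithet == pr$epithet &&
      pl$infraspecific != pr$infraspecific) {
    codes[[length(codes) + 1]] <- out("S", "subspecies_use",
                                      "rank-use deviation")
  }
  if (length(codes) == 0) out(character(0)) else dplyr::bind_rows(codes)
}

#' Summarize an alignment as a discrepancy-count table
#'
#' Counts of each discrepancy type, the total, and the total as a
#' percentage of the larger list's size (rounded to one decimal), the
#' convention used when reporting deviation loads between checklists.
#' Subfamily (F) deviations are excluded: program lists hang below the
#' subfamily level, so they do not affect data integration.
#'
#' @param alignment A `checklist_alignment`.
#' @return One-row tibble: `G`, `S`, `L`, `C`, `U`, `total`, `pct`.
#' @export
summarize_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "checklist_alignment"))
  p <- alignment$pairs
  by_pair <- split(p$dtype, p$pair_id)
  count_type <- function(code) {
    sum(vapply(by_pair, function(z) code %in% unlist(z), logical(1)))
  }
  u <- length(alignment$unmatched_left) + length(alignment$unmatched_right)
  g <- count_type("G")
  s <- count_type("S")
  l <- count_type("L")
  cc <- count_type("C")
  total <- g + s + l + cc + u
  denom <- max(alignment$n_left, alignment$n_right)
  tibble::tibble(
    G = g, S = s, L = l, C = cc, U = u, total = total,
    pct = if (denom > 0) round(100 * total / denom, 1) else NA_real_
  )
}
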
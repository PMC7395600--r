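#' Specification for a synthetic checklist network
#'
#' Describes a network of monitoring programs derived from base authority
#' lists over a shared concept pool, with discrepancies injected at stated
#' per-name rates. Defaults emulate the shape of a real Pollard-walk
#' network: a few hundred shared concepts split across a handful of genera,
#' three base authorities, ten programs, and per-name deviation rates in
#' the low percent range, matching the deviation loads observed between
#' program lists and their bases.
#'
#' @param seed Integer seed; the whole network is reproducible from it.
#' @param n_concepts Number of switchboard concepts.
#' @param n_bases Number of base authority lists.
#' @param n_programs Number of program checklists (>= 2).
#' @param rates Named numeric vector of injection probabilities per
#'   program name: `G` genus substitution, `S` synonym substitution
#'   (curation-resolvable), `L` spelling perturbation, `U` omission,
#'   `C` conglomerate lumping of an eligible congeneric pair.
#' @param lump_rate Probability that a base authority files an eligible
#'   concept pair under a single broad name (duplicated holders), the
#'   authority-level analogue of a program conglomerate.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_concepts = 40L, n_bases = 3L,
                           n_programs = 10L,
                           rates = c(G = 0.02, S = 0.02, L = 0.015,
                                     U = 0.015, C = 0.01),
                           lump_rate = 0.05) {
  full <- c(G = 0, S = 0, L = 0, U = 0, C = 0)
  stopifnot(is.numeric(rates), all(names(rates) %in% names(full)))
  full[names(rates)] <- rates
  if (any(full < 0 | full > 1) || lump_rate < 0 || lump_rate > 1) {
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  }
  if (sum(full) > 1) {
    stop("injection rates must sum to at most 1 (one injection per name)",
         call. = FALSE)
  }
  if (n_programs < 2) stop("need at least two programs", call. = FALSE)
  if ((full[["C"]] > 0 || lump_rate > 0) && n_concepts < 2) {
    stop("conglomerate/lump rates need at least two concepts", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_concepts = as.integer(n_concepts),
                 n_bases = as.integer(n_bases),
                 n_programs = as.integer(n_programs),
                 rates = full, lump_rate = lump_rate),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# pronounceable names from a fixed syllable alphabet; the spelling
# perturbation (final-letter doubling) cannot collide with a synonym
# (built from a disjoint syllable set)
make_words <- function(n, syllables, n_syl = 3) {
  grid <- expand.grid(rep(list(syllables), n_syl), stringsAsFactors = FALSE)
  words <- unique(do.call(paste0, grid))
  if (n > length(words)) stop("syllable pool exhausted", call. = FALSE)
  sample(words, n)
}

#' Generate a synthetic checklist network with known ground truth
#'
#' Builds a switchboard of labelled concepts, base lists covering all of
#' them (optionally filing some congeneric pairs under one broad duplicated
#' holder name), and program checklists derived from their bases with
#' injected discrepancies of the classic six-type typology. Every injection
#' is recorded, so alignment summaries and translation outcomes can be
#' checked against exact expectations.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `mapping` (a `taxon_mapping`) and `truth`, itself a
#'   list: `injections` (one row per injected discrepancy), `counts`
#'   (per-program per-type totals), `curation` (entries resolving the
#'   injected synonym substitutions), and `expected_matches` (per
#'   receiver-name/donor expected match type, derived from the generator's
#'   own concept bookkeeping, independently of the mapping graph).
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, synthesize_impl(spec))
}

synthesize_impl <- function(spec) {
  syl_a <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ru")
  syl_b <- c("sa", "te", "vi", "xo", "zu", "ka", "pe", "mi", "no", "lu")
  n_genera <- max(1L, ceiling(spec$n_concepts / 5))
  genus_names <- make_words(2L * n_genera, syl_a, 3)
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  genera <- cap(genus_names[seq_len(n_genera)])
  alt_genus <- stats::setNames(cap(genus_names[n_genera + seq_len(n_genera)]),
                               genera)
  epithets <- make_words(spec$n_concepts, syl_a, 3)
  synonyms <- stats::setNames(make_words(spec$n_concepts, syl_b, 3), epithets)

  concepts <- tibble::tibble(
    label = epithets,
    genus = genera[((seq_len(spec$n_concepts) - 1) %% n_genera) + 1]
  )
  concepts <- concepts[order(concepts$genus, concepts$label), ]

  rows <- list()
  id_n <- 0L
  add <- function(parent, source, name, rank, note = "") {
    id_n <<- id_n + 1L
    id <- sprintf("T%04d", id_n)
    rows[[id_n]] <<- c(id, parent, source, name, rank, note)
    id
  }

  concept_id <- character(0)
  for (i in seq_len(nrow(concepts))) {
    concept_id[[concepts$label[[i]]]] <-
      add(NA_character_, "switchboard", concepts$label[[i]], "concept",
          paste0("complex=cx-", concepts$genus[[i]]))
  }

  # eligible congeneric pairs: consecutive concepts within a genus, disjoint
  pair_pool <- list()
  for (g in unique(concepts$genus)) {
    lab <- concepts$label[concepts$genus == g]
    k <- seq_len(length(lab) %/% 2)
    for (q in k) pair_pool[[length(pair_pool) + 1]] <-
        c(g, lab[[2 * q - 1]], lab[[2 * q]])
  }

  bases <- sprintf("BASE%d", seq_len(spec$n_bases))
  base_holder <- list()   # base_holder[[base]][[label]] = holder id
  base_lumps <- list()    # base -> list of c(genus, l1, l2)
  for (b in bases) {
    base_holder[[b]] <- character(0)
    base_lumps[[b]] <- list()
    lumped <- character(0)
    for (pr in pair_pool) {
      if (stats::runif(1) < spec$lump_rate) {
        base_lumps[[b]][[length(base_lumps[[b]]) + 1]] <- pr
        lumped <- c(lumped, pr[[2]], pr[[3]])
        broad <- paste(pr[[1]], pr[[2]])  # broad name = first component
        base_holder[[b]][[pr[[2]]]] <- add(concept_id[[pr[[2]]]], b, broad,
                                           "species", "duplicated holder")
        base_holder[[b]][[pr[[3]]]] <- add(concept_id[[pr[[3]]]], b, broad,
                                           "species", "duplicated holder")
      }
    }
    for (i in seq_len(nrow(concepts))) {
      lab <- concepts$label[[i]]
      if (lab %in% lumped) next
      base_holder[[b]][[lab]] <- add(concept_id[[lab]], b,
                                     paste(concepts$genus[[i]], lab), "species")
    }
  }

  programs <- sprintf("PROG%02d", seq_len(spec$n_programs))
  prog_base <- stats::setNames(bases[((seq_len(spec$n_programs) - 1) %%
                                        spec$n_bases) + 1], programs)

  injections <- list()
  prog_sets <- list()   # prog_sets[[p]][[name]] = concept labels (ground truth)
  inject <- function(p, type, concept, base_name, program_name) {
    injections[[length(injections) + 1]] <<- c(p, type, concept, base_name,
                                               program_name)
  }

  types <- c("G", "S", "L", "U", "C", "none")
  for (p in programs) {
    b <- prog_base[[p]]
    prog_sets[[p]] <- list()
    lumped_in_base <- unlist(lapply(base_lumps[[b]], function(z) z[2:3]))

    draw <- function() {
      sample(types, 1, prob = c(spec$rates, 1 - sum(spec$rates)))
    }

    # base-lumped pairs: program inherits the broad name covering both
    for (pr in base_lumps[[b]]) {
      broad <- paste(pr[[1]], pr[[2]])
      add(base_holder[[b]][[pr[[2]]]], p, broad, "species")
      add(base_holder[[b]][[pr[[3]]]], p, broad, "species")
      prog_sets[[p]][[broad]] <- c(pr[[2]], pr[[3]])
    }

    done <- character(0)
    for (i in seq_len(nrow(concepts))) {
      lab <- concepts$label[[i]]
      if (lab %in% lumped_in_base || lab %in% done) next
      g <- concepts$genus[[i]]
      base_name <- paste(g, lab)
      type <- draw()
      if (type == "C") {
        # lump with the genus partner if it is free
        partner <- NULL
        for (pr in pair_pool) {
          if (pr[[2]] == lab && !(pr[[3]] %in% c(lumped_in_base, done))) {
            partner <- pr[[3]]
          }
          if (pr[[3]] == lab && !(pr[[2]] %in% c(lumped_in_base, done))) {
            partner <- pr[[2]]
          }
        }
        if (is.null(partner)) type <- "none" else {
          congl <- paste0(g, " ", min(lab, partner), "/", max(lab, partner))
          add(base_holder[[b]][[lab]], p, congl, "conglomerate")
          add(base_holder[[b]][[partner]], p, congl, "conglomerate")
          prog_sets[[p]][[congl]] <- sort(c(lab, partner))
          done <- c(done, partner)
          inject(p, "C", lab, base_name, congl)
        }
      }
      if (type == "U") {
        inject(p, "U", lab, base_name, NA_character_)
      } else if (type == "G") {
        nm <- paste(alt_genus[[g]], lab)
        add(base_holder[[b]][[lab]], p, nm, "species")
        prog_sets[[p]][[nm]] <- lab
        inject(p, "G", lab, base_name, nm)
      } else if (type == "S") {
        nm <- paste(g, synonyms[[lab]])
        add(base_holder[[b]][[lab]], p, nm, "species")
        prog_sets[[p]][[nm]] <- lab
        inject(p, "S", lab, base_name, nm)
      } else if (type == "L") {
        nm <- paste0(g, " ", lab, substr(lab, nchar(lab), nchar(lab)))
        add(base_holder[[b]][[lab]], p, nm, "species")
        prog_sets[[p]][[nm]] <- lab
        inject(p, "L", lab, base_name, nm)
      } else if (type == "none") {
        add(base_holder[[b]][[lab]], p, base_name, "species")
        prog_sets[[p]][[base_name]] <- lab
      }
      done <- c(done, lab)
    }
  }

  rowm <- do.call(rbind, rows)
  mapping <- new_mapping(tibble::tibble(
    taxon_id = rowm[, 1], parent_id = rowm[, 2], source = rowm[, 3],
    name = rowm[, 4], rank = rowm[, 5], note = rowm[, 6]))

  injm <- do.call(rbind, injections)
  if (is.null(injm)) injm <- matrix(character(0), ncol = 5)
  inj <- tibble::tibble(
    program = injm[, 1], type = injm[, 2], concept = injm[, 3],
    base_name = injm[, 4], program_name = injm[, 5])
  counts <- dplyr::count(inj, .data$program, .data$type, name = "n")
  cur_rows <- inj[inj$type == "S", ]
  curation <- tibble::tibble(
    leftSource = NA_character_, leftName = cur_rows$base_name,
    rightSource = cur_rows$program, rightName = cur_rows$program_name,
    dtype = "S", sSubtype = "synonym", note = "injected synonym"
  )

  expected <- expected_matches_oracle(programs, prog_sets)

  list(mapping = mapping,
       truth = list(injections = inj, counts = counts, curation = curation,
                    expected_matches = expected,
                    prog_sets = prog_sets, prog_base = prog_base))
}

# Brute-force concept-set-relation oracle over the generator's own
# bookkeeping: for every receiver name and donor, enumerate the relation of
# each donor name's concept set to the request (disjoint / within / equal /
# superset) and derive the expected match type. Works purely on label sets,
# never on the mapping graph.
expected_matches_oracle <- function(programs, prog_sets) {
  out <- list()
  for (p in programs) {
    for (nm in names(prog_sets[[p]])) {
      R <- sort(unique(unlist(prog_sets[[p]][[nm]])))
      for (d in setdiff(programs, p)) {
        dsets <- prog_sets[[d]]
        within <- character(0)
        supersets <- character(0)
        for (dn in names(dsets)) {
          S <- sort(unique(unlist(dsets[[dn]])))
          if (length(intersect(S, R)) == 0) next
          if (all(S %in% R)) {
            within <- c(within, dn)
          } else {
            supersets <- c(supersets, dn)
          }
        }
        type <- if (length(within) >= 2) {
          "MM"
        } else if (length(within) == 1) {
          S <- sort(unique(unlist(dsets[[within]])))
          if (identical(S, R) && canonical_key(within) == canonical_key(nm)) {
            "PM"
          } else {
            "CM"
          }
        } else if (length(supersets) >= 1) {
          # donor lump usable only if receiver monitors all its concepts
          S <- sort(unique(unlist(dsets[supersets[[1]]])))
          rest <- setdiff(S, R)
          sibs <- unlist(lapply(prog_sets[[p]], function(z)
            if (length(intersect(z, rest)) > 0) z else NULL))
          if (length(setdiff(rest, sibs)) == 0) "CM+" else "Zero"
        } else {
          "Zero"
        }
        out[[length(out) + 1]] <- c(p, nm, d, type)
      }
    }
  }
  om <- do.call(rbind, out)
  if (is.null(om)) om <- matrix(character(0), ncol = 4)
  tibble::tibble(receiver = om[, 1], receiver_name = om[, 2],
                 donor = om[, 3], expected_type = om[, 4])
}
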
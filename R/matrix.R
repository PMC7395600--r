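#' Build a species-concept integration matrix for a complex
#'
#' Runs [translate()] for every (receiver program, receiver taxon, donor
#' program) combination in which the receiver taxon belongs to the given
#' species complex, and records the match code (`PM`, `CM`, `MM`, `CM+`,
#' `Zero`) plus whether any warning flag accompanied it. Self-comparisons
#' are marked `X` and never translated.
#'
#' @param mapping A `taxon_mapping`.
#' @param complex_id Complex label as tagged on the switchboard
#'   (`complex=<id>` in conceptNote).
#' @param programs Optional character vector fixing program order; defaults
#'   to order of first appearance in the mapping.
#' @return A tibble of class `integration_matrix` with columns
#'   `receiver_program`, `receiver_taxon`, `donor_program`, `code`,
#'   `flagged`, and the `complex_id` attribute.
#' @export
build_matrix <- function(mapping, complex_id, programs = NULL) {
  idx <- mapping_index(mapping)
  cx_concepts <- names(idx$complexes)[!is.na(idx$complexes) &
                                        idx$complexes == complex_id]
  if (length(cx_concepts) == 0) {
    stop("unknown complex '", complex_id, "'", call. = FALSE)
  }
  prog_all <- idx$sources$source_id[idx$sources$role == "program"]
  if (is.null(programs)) programs <- prog_all
  stopifnot(all(programs %in% prog_all))

  rows <- list()
  for (p in programs) {
    keys <- names(idx$occ[[p]])[vapply(idx$occ[[p]], function(z)
      any(z %in% cx_concepts), logical(1))]
    for (k in keys) {
      taxon <- idx$names_raw[[p]][[k]]
      for (d in programs) {
        if (d == p) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            receiver_program = p, receiver_taxon = taxon,
            donor_program = d, code = "X", flagged = FALSE)
          next
        }
        res <- translate_idx(idx, p, k, d)
        rows[[length(rows) + 1]] <- tibble::tibble(
          receiver_program = p, receiver_taxon = taxon,
          donor_program = d, code = res$match_type,
          flagged = nrow(res$flags[[1]]) > 0)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0 || !any(out$code != "X")) {
    stop("complex '", complex_id, "' is not monitored by at least two programs",
         call. = FALSE)
  }
  out <- tibble::new_tibble(out, class = "integration_matrix")
  attr(out, "complex_id") <- complex_id
  attr(out, "programs") <- programs
  out
}

matrix_cell_key <- function(m) {
  paste(m$receiver_program, canonical_key(m$receiver_taxon), m$donor_program,
        sep = "\r")
}

#' Compare an integration matrix against an expected matrix
#'
#' Cell-by-cell comparison on (match code, flag presence) over the
#' off-diagonal cells, the regression harness used to certify a curated
#' mapping: agreement of 100% means the translator reproduces the curators'
#' pre-constructed compatibility matrix exactly.
#'
#' @param actual,expected Integration matrices (same complex, same cells).
#' @param compare_flags Include flag presence in the agreement criterion
#'   (default `TRUE`).
#' @return An object of class `matrix_comparison`: list with `total_cells`,
#'   `agreeing`, `agreement_pct`, and `mismatches` (tibble with expected and
#'   actual code/flag for every disagreeing cell).
#' @export
compare_matrix <- function(actual, expected, compare_flags = TRUE) {
  a <- tibble::as_tibble(actual)[c("receiver_program", "receiver_taxon",
                                   "donor_program", "code", "flagged")]
  e <- tibble::as_tibble(expected)[c("receiver_program", "receiver_taxon",
                                     "donor_program", "code", "flagged")]
  a <- a[a$code != "X", ]
  e <- e[e$code != "X", ]
  a$key <- matrix_cell_key(a)
  e$key <- matrix_cell_key(e)
  if (nrow(a) != nrow(e) || !setequal(a$key, e$key)) {
    stop("matrix shapes differ: ", nrow(a), " vs ", nrow(e),
         " off-diagonal cells with ",
         length(setdiff(e$key, a$key)) + length(setdiff(a$key, e$key)),
         " unshared", call. = FALSE)
  }
  j <- dplyr::inner_join(e, a, by = "key", suffix = c("_expected", "_actual"))
  ok <- j$code_expected == j$code_actual
  if (compare_flags) ok <- ok & (j$flagged_expected == j$flagged_actual)
  mism <- tibble::tibble(
    receiver_program = j$receiver_program_expected[!ok],
    receiver_taxon = j$receiver_taxon_expected[!ok],
    donor_program = j$donor_program_expected[!ok],
    expected_code = j$code_expected[!ok],
    actual_code = j$code_actual[!ok],
    expected_flag = j$flagged_expected[!ok],
    actual_flag = j$flagged_actual[!ok]
  )
  structure(list(
    total_cells = nrow(j),
    agreeing = sum(ok),
    agreement_pct = 100 * sum(ok) / nrow(j),
    mismatches = mism
  ), class = "matrix_comparison")
}

#' @export
print.matrix_comparison <- function(x, ...) {
  cat(sprintf("<matrix_comparison> %d/%d cells agree (%.1f%%)\n",
              x$agreeing, x$total_cells, x$agreement_pct))
  if (nrow(x$mismatches) > 0) {
    cat("mismatches:\n")
    print(x$mismatches)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compare_matrix
#' @param x A `matrix_comparison`.
#' @param ... Unused.
#' @method tidy matrix_comparison
#' @export
tidy.matrix_comparison <- function(x, ...) x$mismatches

#' @rdname compare_matrix
#' @method glance matrix_comparison
#' @export
glance.matrix_comparison <- function(x, ...) {
  tibble::tibble(total_cells = x$total_cells, agreeing = x$agreeing,
                 agreement_pct = x$agreement_pct,
                 mismatched = nrow(x$mismatches))
}

# Expected-matrix CSV interface. Aliases used by curators' hand-built
# matrices are accepted on read (EM -> CM, EM-s -> CM, Com -> CM+,
# Z -> Zero); only canonical codes are emitted.
expected_code_aliases <- c(
  "PM" = "PM", "CM" = "CM", "MM" = "MM", "CM+" = "CM+", "ZERO" = "Zero",
  "Zero" = "Zero", "Z" = "Zero", "X" = "X",
  "EM" = "CM", "EM-s" = "CM", "Com" = "CM+"
)

#' Read an expected integration matrix from CSV
#'
#' Columns: `complexId`, `receiverProgram`, `receiverTaxon`, `donorProgram`,
#' `expectedCode` (`PM|CM|CM+|MM|Zero|X`, plus accepted curator aliases
#' `EM`, `EM-s`, `Com`, `Z`; `ABS` rows are dropped — the receiver does not
#' monitor the taxon, so no request is made), `expectedFlag` (0/1).
#'
#' @param path CSV path.
#' @return An `integration_matrix` tibble.
#' @export
read_expected_matrix <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("complexId", "receiverProgram", "receiverTaxon", "donorProgram",
            "expectedCode", "expectedFlag")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("expected-matrix file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[raw$expectedCode != "ABS", ]
  code <- expected_code_aliases[raw$expectedCode]
  if (anyNA(code)) {
    stop("unknown expected code(s): ",
         paste(unique(raw$expectedCode[is.na(code)]), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    receiver_program = raw$receiverProgram,
    receiver_taxon = raw$receiverTaxon,
    donor_program = raw$donorProgram,
    code = unname(code),
    flagged = raw$expectedFlag == "1"
  )
  out <- tibble::new_tibble(out, class = "integration_matrix")
  attr(out, "complex_id") <- unique(raw$complexId)[1]
  out
}

#' Write an integration matrix to the expected-matrix CSV format
#'
#' @param m An `integration_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  out <- tibble::tibble(
    complexId = attr(m, "complex_id") %||% NA_character_,
    receiverProgram = m$receiver_program,
    receiverTaxon = m$receiver_taxon,
    donorProgram = m$donor_program,
    expectedCode = m$code,
    expectedFlag = as.integer(m$flagged)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Render an integration matrix as a wide text table
#'
#' One row per (receiver program, receiver taxon), one column per donor
#' program; `CM+` and flags shown inline (`*` marks a flagged cell).
#'
#' @param m An `integration_matrix`.
#' @return A wide tibble (printed nicely by default).
#' @export
format_matrix <- function(m) {
  t <- tibble::as_tibble(m)
  t$cell <- paste0(t$code, ifelse(t$flagged, "*", ""))
  tidyr::pivot_wider(
    t[c("receiver_program", "receiver_taxon", "donor_program", "cell")],
    names_from = "donor_program", values_from = "cell"
  )
}

#' Plot an integration matrix
#'
#' Tile heat-map of match codes; flagged cells are outlined.
#'
#' @param object An `integration_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot integration_matrix
#' @export
autoplot.integration_matrix <- function(object, ...) {
  t <- tibble::as_tibble(object)
  t$row <- paste(t$receiver_program, t$receiver_taxon, sep = "\n")
  t$row <- factor(t$row, levels = rev(unique(t$row)))
  t$donor_program <- factor(t$donor_program, levels = unique(t$donor_program))
  t$code <- factor(t$code, levels = c("PM", "CM", "CM+", "MM", "Zero", "X"))
  ggplot2::ggplot(t, ggplot2::aes(x = .data$donor_program, y = .data$row,
                                  fill = .data$code)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = t[t$flagged, ], fill = NA, color = "black",
                       linewidth = 0.9) +
    ggplot2::geom_text(ggplot2::aes(label = .data$code), size = 3) +
    ggplot2::scale_fill_manual(values = c(
      PM = "#66c2a5", CM = "#abdda4", `CM+` = "#fee08b", MM = "#fdae61",
      Zero = "#eeeeee", X = "#cccccc"), drop = FALSE) +
    ggplot2::labs(x = "Donor program", y = "Receiver program / taxon",
                  fill = "Match") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
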
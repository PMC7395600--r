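# Independent oracles, deliberately implemented apart from the package code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook dynamic-programming Levenshtein distance
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L,
        d[i, j] + (x[[i]] != y[[j]])
      )
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# brute-force concept-set-relation oracle: classifies a request purely by
# enumerating the relation (disjoint / within / equal / superset) of every
# donor name's ground-truth concept set to the receiver name's set; for
# synthetic networks (no interpretation deviations) this fully determines
# the expected match type
relation_oracle <- function(sets_receiver, receiver_name, sets_donor) {
  R <- sort(unique(sets_receiver[[receiver_name]]))
  rel <- vapply(names(sets_donor), function(dn) {
    S <- sort(unique(sets_donor[[dn]]))
    common <- intersect(S, R)
    if (length(common) == 0) "disjoint"
    else if (identical(S, R)) "equal"
    else if (all(S %in% R)) "within"
    else "superset"
  }, character(1))
  eq <- names(rel)[rel == "equal"]
  within <- names(rel)[rel %in% c("equal", "within")]
  sup <- names(rel)[rel == "superset"]
  if (length(within) >= 2) return("MM")
  if (length(within) == 1) {
    same_name <- tolower(within) == tolower(receiver_name)
    return(if (length(eq) == 1 && same_name) "PM" else "CM")
  }
  if (length(sup) >= 1) {
    S <- sort(unique(sets_donor[[sup[[1]]]]))
    rest <- setdiff(S, sort(unique(sets_receiver[[receiver_name]])))
    covered <- rest %in% unlist(sets_receiver)
    return(if (all(covered)) "CM+" else "Zero")
  }
  "Zero"
}

# strip container attributes so record-level identity can be asserted
strip_records <- function(m) {
  d <- as.data.frame(m)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

tiny_rates <- c(G = 0.08, S = 0.08, L = 0.08, U = 0.08, C = 0.08)

# small hand-built mapping: one concept complex, a splitting and a lumping
# base, two programs
toy_mapping <- function() {
  rows <- tibble::tribble(
    ~taxon_id, ~parent_id, ~source,       ~name,        ~rank,      ~note,
    "T0001",   NA,         "switchboard", "alpha",      "concept",  "complex=cx-toy",
    "T0002",   NA,         "switchboard", "beta",       "concept",  "complex=cx-toy",
    "T0101",   "T0001",    "SPLIT",       "Genus alpha", "species", "",
    "T0102",   "T0002",    "SPLIT",       "Genus beta",  "species", "",
    "T0201",   "T0001",    "LUMP",        "Genus alpha", "species", "duplicated holder",
    "T0202",   "T0002",    "LUMP",        "Genus alpha", "species", "duplicated holder",
    "T0301",   "T0101",    "P1",          "Genus alpha", "species", "",
    "T0302",   "T0102",    "P1",          "Genus beta",  "species", "",
    "T0401",   "T0201",    "P2",          "Genus alpha", "species", "",
    "T0402",   "T0202",    "P2",          "Genus alpha", "species", ""
  )
  new_mapping(rows)
}
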
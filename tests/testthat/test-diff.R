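test_that("pair classification reproduces the canonical discrepancy types", {
  # deliberate synonym substitution resolved by curation
  cur <- curation_table("Piruna cingo", "Piruna aea", "S",
                        s_subtype = "synonym")
  cls <- classify_pair("Piruna cingo", "Piruna aea", cur)
  expect_equal(cls$code, "S")
  expect_equal(cls$s_subtype, "synonym")

  # conglomerate pooling two field-indistinguishable species
  cls <- classify_pair(c("Colias eurytheme", "Colias philodice"),
                       "Colias eurytheme/philodice")
  expect_equal(cls$code, "C")

  # one-sided record
  cls <- classify_pair("Kisutam syllis", character(0))
  expect_equal(cls$code, "U")

  # spelling variant
  cls <- classify_pair("Atrytonopsis edwardsi", "Atrytonopsis edwardsii")
  expect_equal(cls$code, "L")

  # genus deviation, same epithet
  cls <- classify_pair("Plebejus melissa", "Lycaeides melissa")
  expect_equal(cls$code, "G")

  # subspecies-use deviation
  cls <- classify_pair("Speyeria cybele leto", "Speyeria cybele")
  expect_equal(cls$code, "S")
  expect_equal(cls$s_subtype, "subspecies_use")

  # exact match carries no discrepancy
  expect_equal(nrow(classify_pair("Hesperia comma", "Hesperia  comma")), 0)

  # both genus and epithet differ without curation: two candidate codes
  cls <- classify_pair("Hesperia comma", "Ochlodes sylvanoides")
  expect_setequal(cls$code, c("G", "S"))

  expect_error(classify_pair(character(0), character(0)), "at least one side")
})

test_that("pair classification is symmetric for two-name comparisons", {
  pairs <- list(
    c("Atrytonopsis edwardsi", "Atrytonopsis edwardsii"),
    c("Plebejus melissa", "Lycaeides melissa"),
    c("Piruna cingo", "Piruna aea"),
    c("Speyeria cybele leto", "Speyeria cybele")
  )
  for (p in pairs) {
    expect_setequal(classify_pair(p[[1]], p[[2]])$code,
                    classify_pair(p[[2]], p[[1]])$code)
  }
})

test_that("identical checklists align perfectly", {
  nms <- c("Hesperia comma", "Piruna aea", "Colias eurytheme",
           "Colias philodice", "Celastrina ladon")
  al <- align_checklists(nms, nms)
  expect_equal(nrow(al$pairs), 5)
  expect_equal(length(al$unmatched_left), 0)
  expect_equal(length(al$unmatched_right), 0)
  s <- summarize_alignment(al)
  expect_equal(unlist(s[c("G", "S", "L", "C", "U", "total")]),
               c(G = 0, S = 0, L = 0, C = 0, U = 0, total = 0))
})

test_that("heuristic alignment proposes L, G, C and leaves the rest unmatched", {
  base <- c("Atrytonopsis edwardsii", "Lycaeides melissa", "Colias eurytheme",
            "Colias philodice", "Kisutam syllis", "Hesperia comma")
  prog <- c("Atrytonopsis edwardsi", "Plebejus melissa",
            "Colias eurytheme/philodice", "Hesperia comma")
  al <- align_checklists(base, prog)
  s <- summarize_alignment(al)
  expect_equal(s$L, 1)
  expect_equal(s$G, 1)
  expect_equal(s$C, 1)
  expect_equal(s$U, 1)
  expect_equal(al$unmatched_left, "Kisutam syllis")
  expect_equal(s$pct, round(100 * s$total / 6, 1))
})

test_that("every record lands exactly once across pairs and unmatched", {
  for (seed in c(3, 8)) {
    net <- synthesize(synthetic_spec(seed = seed, n_concepts = 14,
                                     n_bases = 2, n_programs = 3,
                                     rates = tiny_rates, lump_rate = 0.2))
    p <- "PROG02"
    b <- net$truth$prog_base[[p]]
    left <- mapping_checklist(net$mapping, b)
    right <- mapping_checklist(net$mapping, p)
    al <- align_checklists(left, right, net$truth$curation)
    seen_left <- c(unique(al$pairs$left_name), al$unmatched_left)
    seen_right <- c(unique(al$pairs$right_name), al$unmatched_right)
    expect_setequal(seen_left, unique(left$name))
    expect_equal(anyDuplicated(seen_left), 0)
    expect_setequal(seen_right, unique(right$name))
    expect_equal(anyDuplicated(seen_right), 0)
  }
})

test_that("injected discrepancy counts are recovered exactly", {
  for (seed in c(2, 9, 17)) {
    net <- synthesize(synthetic_spec(seed = seed, n_concepts = 18,
                                     n_bases = 2, n_programs = 4,
                                     rates = tiny_rates, lump_rate = 0.15))
    for (p in names(net$truth$prog_base)) {
      al <- align_checklists(
        mapping_checklist(net$mapping, net$truth$prog_base[[p]]),
        mapping_checklist(net$mapping, p),
        net$truth$curation)
      s <- summarize_alignment(al)
      gt <- net$truth$counts[net$truth$counts$program == p, ]
      want <- function(t) if (t %in% gt$type) gt$n[gt$type == t] else 0L
      expect_equal(s$G, want("G"), label = paste(seed, p, "G"))
      expect_equal(s$L, want("L"), label = paste(seed, p, "L"))
      expect_equal(s$C, want("C"), label = paste(seed, p, "C"))
      expect_equal(s$U, want("U"), label = paste(seed, p, "U"))
      expect_equal(s$S, want("S"), label = paste(seed, p, "S"))
    }
  }
})

test_that("synonym injections without curation surface as unresolved S", {
  net <- synthesize(synthetic_spec(seed = 4, n_concepts = 18, n_bases = 2,
                                   n_programs = 3,
                                   rates = c(S = 0.25), lump_rate = 0))
  p <- net$truth$injections$program[net$truth$injections$type == "S"][1]
  al <- align_checklists(
    mapping_checklist(net$mapping, net$truth$prog_base[[p]]),
    mapping_checklist(net$mapping, p),
    curation = NULL)
  s_pairs <- al$pairs[vapply(al$pairs$dtype, function(z) "S" %in% z,
                             logical(1)), ]
  expect_gt(nrow(s_pairs), 0)
  expect_true(all(s_pairs$note == "unresolved"))
})

test_that("curation tables reject contradictions and dangling references", {
  expect_error(
    curation_table(c("Piruna cingo", "Piruna cingo"),
                   c("Piruna aea", "Piruna aea"), c("S", "L")),
    "contradictory")
  cur <- curation_table("Lethe anthedon", "Enodia anthedon", "G")
  expect_error(align_checklists("Hesperia comma", "Hesperia comma", cur),
               "absent from both")
})
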
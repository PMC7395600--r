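test_that("occurrence sets follow every same-named record upward", {
  m <- celastrina_fixture()
  expect_equal(concepts_of(m, "Cascades", "Celastrina lucia")$label, "lucia")
  expect_setequal(concepts_of(m, "Iowa", "Celastrina ladon")$label,
                  c("ladon", "neglecta"))
  expect_setequal(concepts_of(m, "Illinois", "Celastrina ladon/neglecta")$label,
                  c("ladon", "neglecta"))
  expect_equal(concepts_of(m, "OrangeCounty", "Celastrina ladon echo")$label,
               "echo")
  expect_error(concepts_of(m, "Iowa", "Celastrina echo"), "not on the")
  expect_error(concepts_of(m, "Atlantis", "Celastrina ladon"),
               "unknown source")
})

test_that("interpretation sets widen to the authority's circumscription", {
  m <- celastrina_fixture()
  # a NABA-based program's broad name means everything the authority files
  # under it, even concepts outside the program's range
  expect_setequal(interpretation_of(m, "Iowa", "Celastrina ladon")$label,
                  c("ladon", "neglecta", "lucia", "echo", "humulus",
                    "serotina", "idella"))
  # a splitting authority's name stays narrow
  expect_equal(interpretation_of(m, "Florida", "Celastrina ladon")$label,
               "ladon")
  # Ohio's deviation name has no base-list name to widen through
  expect_equal(interpretation_of(m, "Ohio", "Celastrina neglecta")$label,
               "neglecta")
  # curated scope override for the Orange County trinomial
  expect_setequal(
    interpretation_of(m, "OrangeCounty", "Celastrina ladon echo")$label,
    c("ladon", "lucia", "echo"))
})

test_that("holder duplication creates distinct same-named records once each", {
  m <- celastrina_fixture()
  idx_labels <- concepts_of(m, "NABA", "Celastrina ladon")$concept_id
  serotina <- idx_labels[[6]]

  m2 <- add_holder(m, "OW", "Celastrina serotina", serotina,
                   note = "holder added for a previously untreated taxon")
  ow <- mapping_checklist(m2, "OW")
  expect_equal(sum(ow$canon == "Celastrina serotina"), 1)
  expect_error(add_holder(m2, "OW", "Celastrina serotina", serotina),
               "already present")

  # same name under two concepts -> two records, distinct ids
  ladon_id <- concepts_of(m, "switchboard", "ladon")$concept_id
  m3 <- add_holder(m2, "OW", "Celastrina serotina", ladon_id)
  ow <- mapping_checklist(m3, "OW")
  hits <- ow[ow$canon == "Celastrina serotina", ]
  expect_equal(nrow(hits), 2)
  expect_equal(length(unique(hits$taxon_id)), 2)

  expect_error(add_holder(m, "Iowa", "Celastrina serotina", serotina),
               "not a base list")
  expect_error(add_holder(m, "OW", "Celastrina serotina", "T9999"),
               "unknown switchboard concept")

  # locality: unrelated lookups are untouched by holder insertion
  expect_identical(concepts_of(m, "Iowa", "Celastrina ladon"),
                   concepts_of(m3, "Iowa", "Celastrina ladon"))
  expect_identical(
    strip_records(build_matrix(m, celastrina_complex_id())),
    strip_records(build_matrix(m3, celastrina_complex_id()))
  )
})

test_that("validation catches cross-role links and cycles", {
  m <- celastrina_fixture()
  expect_equal(nrow(validate_mapping(m)), 0)

  rec <- tibble::as_tibble(m)[, c("taxon_id", "parent_id", "source", "name",
                                  "rank", "note")]
  # a program record parenting into a base other than its declared one
  wrong <- rec
  pelham_echo <- wrong$taxon_id[wrong$source == "Pelham" &
                                  wrong$name == "Celastrina echo"]
  wrong$parent_id[wrong$source == "Florida"][1] <- pelham_echo
  v <- validate_mapping(new_mapping(wrong, validate = FALSE))
  expect_true(any(v$kind == "cross_role"))

  # two records forming a parent cycle
  cyc <- rec
  a <- which(cyc$source == "NABA")[1]
  b <- which(cyc$source == "NABA")[2]
  cyc$parent_id[a] <- cyc$taxon_id[b]
  cyc$parent_id[b] <- cyc$taxon_id[a]
  v <- validate_mapping(new_mapping(cyc, validate = FALSE))
  expect_true(any(v$kind == "cycle"))
})

test_that("upward closure reaches the switchboard within two hops", {
  net <- synthesize(synthetic_spec(seed = 11, n_concepts = 15, n_bases = 3,
                                   n_programs = 4, rates = tiny_rates,
                                   lump_rate = 0.2))
  m <- net$mapping
  progs <- mapping_sources(m)$source_id[mapping_sources(m)$role == "program"]
  for (p in progs) {
    for (n in unique(mapping_checklist(m, p)$canon)) {
      cx <- concepts_of(m, p, n)
      expect_gte(nrow(cx), 1)
      expect_true(all(cx$concept_id %in%
                        m$taxon_id[m$source == "switchboard"]))
    }
  }
})
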
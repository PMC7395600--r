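m <- celastrina_fixture()

test_that("the worked translation requests resolve as curated", {
  r <- translate(m, "Iowa", "Celastrina ladon", "Ohio")
  expect_equal(r$match_type, "MM")
  expect_equal(r$donor_names[[1]], c("Celastrina ladon", "Celastrina neglecta"))

  r <- translate(m, "Cascades", "Celastrina echo", "MPG")
  expect_equal(r$match_type, "PM")
  expect_equal(r$donor_names[[1]], "Celastrina echo")

  r <- translate(m, "Colorado", "Celastrina humulus", "Florida")
  expect_equal(r$match_type, "Zero")
  expect_equal(r$donor_names[[1]], character(0))
  expect_equal(r$message,
               "There is no match in this list (species presumed absent)")

  r <- translate(m, "Ohio", "Celastrina ladon", "Illinois")
  expect_equal(r$match_type, "CM+")
  expect_equal(r$donor_names[[1]], "Celastrina ladon/neglecta")
  expect_equal(r$required_receiver_siblings[[1]], "Celastrina neglecta")
  expect_gt(nrow(r$flags[[1]]), 0)
})

test_that("an unknown receiver name is an error, not a Zero", {
  expect_error(translate(m, "Iowa", "Celastrina lucia", "Ohio"), "not on the")
  expect_error(translate(m, "Nowhere", "Celastrina ladon", "Ohio"),
               "unknown receiver")
  expect_error(translate(m, "Iowa", "Celastrina ladon", "Nowhere"),
               "unknown donor")
})

test_that("self-translation is the identity perfect match", {
  for (p in celastrina_programs()$source_id) {
    for (n in unique(mapping_checklist(m, p)$name)) {
      r <- translate(m, p, n, p)
      expect_equal(r$match_type, "PM")
      expect_equal(r$donor_names[[1]], n)
    }
  }
})

test_that("translation is deterministic and multiple matches are sorted", {
  a <- translate(m, "Illinois", "Celastrina ladon/neglecta", "Cascades")
  b <- translate(m, "Illinois", "Celastrina ladon/neglecta", "Cascades")
  expect_identical(a, b)
  expect_equal(a$match_type, "MM")
  expect_identical(a$donor_names[[1]], sort(a$donor_names[[1]]))
})

test_that("asymmetric requests are flagged, symmetric ones are not", {
  f <- check_symmetry(m, "Illinois", "Celastrina ladon/neglecta", "Ohio")
  expect_equal(f$kind, "asymmetry")

  expect_equal(nrow(check_symmetry(m, "Cascades", "Celastrina echo", "MPG")), 0)
  expect_equal(
    nrow(check_symmetry(m, "OrangeCounty", "Celastrina ladon echo", "MPG")), 0)
  expect_equal(
    nrow(check_symmetry(m, "MPG", "Celastrina echo", "OrangeCounty")), 0)
})

test_that("a Zero means no usable shared concept at the donor", {
  progs <- celastrina_programs()$source_id
  for (p in progs) {
    for (n in unique(mapping_checklist(m, p)$canon)) {
      R <- interpretation_of(m, p, n)$concept_id
      own <- concepts_of(m, p, n)$concept_id
      for (d in setdiff(progs, p)) {
        r <- translate(m, p, n, d, flag_symmetry = FALSE)
        donor_cl <- mapping_checklist(m, d)
        usable <- FALSE
        for (dn in unique(donor_cl$canon)) {
          O_d <- concepts_of(m, d, dn)$concept_id
          if (length(intersect(O_d, R)) == 0) next
          receiver_universe <- unlist(lapply(
            unique(mapping_checklist(m, p)$canon),
            function(z) concepts_of(m, p, z)$concept_id))
          if (length(setdiff(O_d, union(R, receiver_universe))) == 0) {
            usable <- TRUE
          }
        }
        expect_equal(r$match_type == "Zero", !usable,
                     label = paste(p, n, "->", d))
      }
    }
  }
})

test_that("match classification agrees with the set-relation oracle on
           synthetic networks without interpretation deviations", {
  for (seed in 1:25) {
    net <- synthesize(synthetic_spec(seed = seed, n_concepts = 10,
                                     n_bases = 2, n_programs = 3,
                                     rates = tiny_rates, lump_rate = 0.2))
    sets <- net$truth$prog_sets
    em <- net$truth$expected_matches
    for (i in seq_len(nrow(em))) {
      want <- relation_oracle(sets[[em$receiver[[i]]]], em$receiver_name[[i]],
                              sets[[em$donor[[i]]]])
      got <- translate(net$mapping, em$receiver[[i]], em$receiver_name[[i]],
                       em$donor[[i]], flag_symmetry = FALSE)$match_type
      expect_equal(got, want,
                   label = paste(seed, em$receiver[[i]], em$receiver_name[[i]],
                                 "->", em$donor[[i]]))
    }
  }
})

test_that("results serialize to the documented JSON shape", {
  r <- translate(m, "Iowa", "Celastrina ladon", "Ohio")
  j <- jsonlite::fromJSON(match_json(r))
  expect_equal(j$match_type, "MM")
  expect_equal(j$donor_names, c("Celastrina ladon", "Celastrina neglecta"))
  expect_equal(j$receiver, "Iowa")
  expect_true(all(c("kind", "message") %in% names(j$flags)))
})
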
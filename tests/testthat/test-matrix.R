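test_that("the built matrix reproduces the curated expectation exactly", {
  m <- celastrina_fixture()
  act <- build_matrix(m, celastrina_complex_id(),
                      programs = celastrina_programs()$source_id)
  cmpr <- compare_matrix(act, expected_celastrina_matrix())
  expect_equal(cmpr$agreement_pct, 100)
  expect_equal(nrow(cmpr$mismatches), 0)
  # 14 receiver (program, taxon) rows x 10 donors, minus 14 diagonal cells
  expect_equal(cmpr$total_cells, 126)
})

test_that("a matrix compared to itself is in full agreement", {
  e <- expected_celastrina_matrix()
  cmpr <- compare_matrix(e, e)
  expect_equal(cmpr$agreement_pct, 100)
  expect_equal(glance(cmpr)$mismatched, 0)
  expect_equal(nrow(tidy(cmpr)), 0)
})

test_that("program order does not change cell content", {
  m <- celastrina_fixture()
  progs <- celastrina_programs()$source_id
  a <- build_matrix(m, celastrina_complex_id(), programs = progs)
  b <- build_matrix(m, celastrina_complex_id(), programs = rev(progs))
  expect_equal(compare_matrix(a, b)$agreement_pct, 100)
})

test_that("removing one program-to-holder link perturbs exactly that
           program's cells", {
  m <- celastrina_fixture()
  rec <- tibble::as_tibble(m)[, c("taxon_id", "parent_id", "source", "name",
                                  "rank", "note")]
  neglecta <- rec$taxon_id[rec$source == "switchboard" &
                             rec$name == "neglecta"]
  holder <- rec$taxon_id[rec$source == "NABA" & rec$parent_id == neglecta]
  drop <- which(rec$source == "Iowa" & rec$parent_id %in% holder)
  expect_equal(length(drop), 1)
  m2 <- new_mapping(rec[-drop, ])

  cmpr <- compare_matrix(build_matrix(m2, celastrina_complex_id()),
                         expected_celastrina_matrix())
  expect_lt(cmpr$agreement_pct, 100)
  expect_gt(nrow(cmpr$mismatches), 0)
  involved <- cmpr$mismatches$receiver_program == "Iowa" |
    cmpr$mismatches$donor_program == "Iowa"
  expect_true(all(involved))
})

test_that("single-program complexes yield all-Zero donor columns", {
  rows <- tibble::tribble(
    ~taxon_id, ~parent_id, ~source,       ~name,         ~rank,     ~note,
    "T0001",   NA,         "switchboard", "solus",       "concept", "complex=cx-solo",
    "T0002",   NA,         "switchboard", "alius",       "concept", "complex=cx-other",
    "T0101",   "T0001",    "BASE1",       "Genus solus", "species", "",
    "T0102",   "T0002",    "BASE1",       "Genus alius", "species", "",
    "T0201",   "T0101",    "P1",          "Genus solus", "species", "",
    "T0301",   "T0102",    "P2",          "Genus alius", "species", ""
  )
  m <- new_mapping(rows)
  mx <- build_matrix(m, "cx-solo")
  off <- tibble::as_tibble(mx)[mx$code != "X", ]
  expect_true(all(off$code == "Zero"))
  expect_error(build_matrix(m, "cx-missing"), "unknown complex")
})

test_that("expected-matrix CSV reading honours curator code aliases", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "complexId,receiverProgram,receiverTaxon,donorProgram,expectedCode,expectedFlag",
    "cx,A,Genus alpha,B,EM,1",
    "cx,A,Genus alpha,C,EM-s,0",
    "cx,A,Genus alpha,D,Com,1",
    "cx,A,Genus alpha,E,Z,1",
    "cx,B,Genus beta,A,ABS,0",
    "cx,A,Genus alpha,A,X,0"
  ), path)
  e <- read_expected_matrix(path)
  expect_equal(nrow(e), 5)  # the ABS row is dropped: no request is made
  expect_equal(e$code[e$donor_program %in% c("B", "C")], c("CM", "CM"))
  expect_equal(e$code[e$donor_program == "D"], "CM+")
  expect_equal(e$code[e$donor_program == "E"], "Zero")
})

test_that("matrix round trip through CSV preserves codes and flags", {
  e <- expected_celastrina_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(e, path)
  e2 <- read_expected_matrix(path)
  expect_equal(compare_matrix(e, e2)$agreement_pct, 100)
})

test_that("shape mismatches are a comparison error", {
  e <- expected_celastrina_matrix()
  trimmed <- tibble::as_tibble(e)[e$receiver_program != "Iowa", ]
  expect_error(compare_matrix(trimmed, e), "shapes differ")
})

test_that("rendering produces a wide table and a ggplot", {
  e <- expected_celastrina_matrix()
  w <- format_matrix(e)
  expect_equal(nrow(w), 14)
  expect_true(all(celastrina_programs()$source_id %in% names(w)))
  p <- ggplot2::autoplot(e)
  expect_s3_class(p, "ggplot")
})
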
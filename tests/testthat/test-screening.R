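# a minimal hand-built filter-set object
mini_sets <- function() {
  df <- function(sub_id, query) data.frame(sub_id = sub_id, name = sub_id,
                                           query = query,
                                           stringsAsFactors = FALSE)
  structure(list(
    untolerated = df("u_cf3", "C(F)(F)F"),
    tolerated = df(c("t_tetrazole", "t_nitrile"),
                   c("c1nnn[nH]1", "C#N")),
    inner = df("i_benzene", "c1ccccc1"),
    outer = df(c("o_piperazine", "o_thiophene", "o_morpholine"),
               c("C1CNCCN1", "c1ccsc1", "C1COCCN1"))
  ), class = "capa_filter_sets")
}

lib_df <- function(...) {
  smi <- c(...)
  data.frame(compound_id = names(smi) %||% character(0),
             smiles = unname(smi) %||% character(0),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stereo deduplication keeps the first representative", {
  lib <- lib_df(a = "C[C@H](N)C(=O)O", b = "C[C@@H](N)C(=O)O", c = "CCO")
  r <- dedup_stereo(lib)
  expect_equal(r$kept$compound_id, c("a", "c"))
  expect_equal(r$removed$compound_id, "b")
  # all-distinct library passes unchanged
  lib2 <- lib_df(x = "CCO", y = "CCN", z = "CCC")
  r2 <- dedup_stereo(lib2)
  expect_equal(r2$kept[, c("compound_id", "smiles")], lib2)
  expect_equal(nrow(r2$removed), 0)
})

test_that("exclusion and inclusion filters count distinct substructures", {
  sets <- mini_sets()
  lib <- lib_df(
    clean   = "CCC1CNCCN1",                         # one outer
    unt     = "CC(F)(F)F",                          # untolerated hit
    one_tol = "CCC(c1nnn[nH]1)C1CNCCN1",            # 1 tolerated + outer
    two_tol = "CC(c1nnn[nH]1)C(C#N)C1CNCCN1",       # 2 tolerated
    inner   = "CC(c1ccccc1)C1CNCCN1",               # inner hit
    no_out  = "CCCCCC")
  r <- filter_untolerated(lib, sets)
  expect_equal(r$removed$compound_id, "unt")
  r <- filter_tolerated(r$kept, sets, max_tolerated = 1)
  expect_equal(r$removed$compound_id, "two_tol")   # one tolerated hit is kept
  expect_true("one_tol" %in% r$kept$compound_id)
  r <- filter_inner(r$kept, sets)
  expect_equal(r$removed$compound_id, "inner")
  r <- require_outer(r$kept, sets)
  expect_equal(r$removed$compound_id, "no_out")
  expect_setequal(r$kept$compound_id, c("clean", "one_tol"))
})

test_that("candidate scoring ranks by outer count with id tie-break", {
  sets <- mini_sets()
  lib <- lib_df(
    b_two = "CC(C1CNCCN1)CC(c1ccsc1)C",     # piperazine + thiophene
    a_one = "CCC1CNCCN1",
    c_two = "CC(C1CNCCN1)CC(C1COCCN1)C")
  sc <- score_candidates(lib, sets)
  expect_equal(sc$compound_id, c("b_two", "c_two", "a_one"))
  expect_equal(sc$outer_count, c(2L, 2L, 1L))
  expect_equal(attr(sc, "histogram"), c("1" = 1L, "2" = 2L))
  expect_true(all(sc$outer_count >= 1))
})

test_that("composition labels distinguish overlap patterns", {
  # single matched substructure
  sets <- mini_sets()
  sc <- score_candidates(lib_df(s = "CCC1CNCCN1"), sets)
  expect_equal(sc$composition, "single")
  # two substructures on disjoint atoms
  sc <- score_candidates(lib_df(d = "CC(C1CNCCN1)CC(c1ccsc1)C"), sets)
  expect_equal(sc$composition, "distributed")
  # overlapping: a piperazine-matching ring also contains the CNC motif
  sets2 <- mini_sets()
  sets2$outer <- rbind(sets2$outer,
                       data.frame(sub_id = "o_cnc", name = "o_cnc",
                                  query = "CNC", stringsAsFactors = FALSE))
  sc <- score_candidates(lib_df(o = "CCCC1CNCCN1"), sets2)
  expect_equal(sc$composition, "concentrated")
  # mixed: overlapping pair plus a disjoint thiophene
  sc <- score_candidates(lib_df(m = "CC(C1CNCCN1)CC(c1ccsc1)C"), sets2)
  expect_equal(sc$composition, "mixed")
})

test_that("cascade bookkeeping is exact, nested and idempotent", {
  sc <- generate_screening(small_screen_spec(), verify = "none")
  rep <- run_cascade(sc$library, sc$sets)
  st <- rep$stages
  # in/out identity at every stage
  for (k in seq_len(nrow(st) - 1)) {
    expect_equal(st$n_in[k + 1], st$n_in[k] - st$n_removed[k])
  }
  # matches the planted design
  expect_equal(st, attr(sc$ledger, "expected_stages"))
  expect_equal(rep$histogram, attr(sc$ledger, "expected_histogram"))
  expect_equal(sum(rep$histogram), nrow(rep$survivors))
  # survivor sets nested: survivors survive a re-run unchanged (idempotence
  # past the dedup stage)
  lib2 <- sc$library[sc$library$compound_id %in%
                       rep$survivors$compound_id, ]
  rep2 <- run_cascade(lib2, sc$sets)
  expect_setequal(rep2$survivors$compound_id, rep$survivors$compound_id)
  expect_true(all(rep2$stages$n_removed[-1] == 0))
})

test_that("library order changes neither stage counts nor the survivor set", {
  sc <- generate_screening(small_screen_spec(seed = 9), verify = "none")
  rep1 <- run_cascade(sc$library, sc$sets)
  perm <- withr::with_seed(2, sample(nrow(sc$library)))
  rep2 <- run_cascade(sc$library[perm, ], sc$sets)
  expect_equal(rep1$stages[, c("n_in", "n_removed")],
               rep2$stages[, c("n_in", "n_removed")])
  # survivor *keys* agree even though duplicate representatives may differ
  key1 <- sort(make_structure_key(rep1$survivors$smiles))
  key2 <- sort(make_structure_key(rep2$survivors$smiles))
  expect_equal(key1, key2)
})

test_that("empty library passes all six stages with zero counts", {
  sets <- mini_sets()
  rep <- run_cascade(lib_df(), sets)
  expect_equal(nrow(rep$stages), 6)
  expect_true(all(rep$stages$n_in == 0))
  expect_true(all(rep$stages$n_removed == 0))
  expect_equal(nrow(rep$survivors), 0)
})

test_that("screening reports serialize to JSON and CSV", {
  sc <- generate_screening(small_screen_spec(), verify = "none")
  rep <- run_cascade(sc$library, sc$sets)
  json <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_screening_report(rep, json, csv)
  parsed <- jsonlite::read_json(json)
  expect_length(parsed$stages, 6)
  expect_equal(parsed$stages[[1]]$n_in, rep$stages$n_in[1])
  hits <- utils::read.csv(csv)
  expect_equal(nrow(hits), nrow(rep$survivors))
})
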
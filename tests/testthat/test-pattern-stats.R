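test_that("binary matrix records presence, including degenerate shapes", {
  d <- make_profile_compounds(list(a = c(1, 1, 1)), smiles = "Cc1ccccc1")
  cat1 <- make_catalogue("s1", "c1ccccc1")
  m <- suppressMessages(build_matrix(d, cat1))
  expect_identical(m, matrix(TRUE, 1, 1,
                             dimnames = list("a", "s1")))
  # empty compound list: 0-row matrix, no error
  d0 <- d[0, , drop = FALSE]
  m0 <- suppressMessages(build_matrix(d0, cat1))
  expect_equal(dim(m0), c(0L, 1L))
})

test_that("planted column sums are recovered exactly", {
  g <- generate(small_synth_spec(), verify = "none")
  m <- suppressMessages(build_matrix(g$compounds, g$substructures))
  expect_equal(colSums(m)[names(g$ledger$column_sums)],
               g$ledger$column_sums + 0)
})

test_that("percentages implement the normalized formula with extremes", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE,    # s_all in full group 1
                FALSE, FALSE, FALSE, FALSE), # s_none nowhere
              ncol = 2, dimnames = list(ids, c("s_all", "s_none")))
  cls <- stats::setNames(
    factor(c("SUPERIOR_CLASS7", "SUPERIOR_CLASS7", "REAL_CLASS0",
             "REAL_CLASS0"), levels = activity_classes()), ids)
  tab <- suppressWarnings(distribution_table(m, cls))
  expect_true(all(tab$pct >= 0 & tab$pct <= 100))
  expect_equal(tab$pct[tab$sub_id == "s_all" &
                         tab$group == "SUPERIOR_CLASS7"], 100)
  expect_equal(tab$pct[tab$sub_id == "s_all" & tab$group == "REAL_CLASS0"], 0)
  expect_true(all(tab$pct[tab$sub_id == "s_none"] == 0))
  # indicator-sum identity: group hit counts add up to the column total
  expect_equal(sum(tab$n_hits[tab$sub_id == "s_all"]), sum(m[, "s_all"]))
  # empty groups warn and report 0
  expect_warning(distribution_table(m, cls), "empty group")
})

test_that("5 of 36 reports as 13.9 percent", {
  ids <- paste0("c", 1:36)
  m <- matrix(c(rep(TRUE, 5), rep(FALSE, 31)), ncol = 1,
              dimnames = list(ids, "s"))
  cls <- stats::setNames(factor(rep("MEDIUM_CLASS7", 36),
                                levels = activity_classes()), ids)
  tab <- suppressWarnings(distribution_table(m, cls))
  pct <- tab$pct[tab$group == "MEDIUM_CLASS7"]
  expect_equal(report_pct(pct), 13.9)
  expect_equal(pct, 500 / 36)  # unrounded internally
})

test_that("percentages are invariant under compound reordering", {
  g <- generate(small_synth_spec(), verify = "none")
  m <- suppressMessages(build_matrix(g$compounds, g$substructures))
  cl <- classify(g$compounds)
  t1 <- suppressWarnings(distribution_table(m, cl))
  perm <- withr::with_seed(4, sample(nrow(m)))
  t2 <- suppressWarnings(distribution_table(m[perm, , drop = FALSE], cl))
  expect_equal(t1, t2)
})

test_that("group ratios apply the division-by-zero policy", {
  ids <- c("a", "b", "c", "d")
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE,    # s1: 50% vs 50%... see below
                TRUE, TRUE, FALSE, FALSE,    # s2: 100% vs 0%
                FALSE, FALSE, FALSE, FALSE), # s3: absent everywhere
              ncol = 3, dimnames = list(ids, c("s1", "s2", "s3")))
  cls <- stats::setNames(
    factor(c("SUPERIOR_CLASS7", "SUPERIOR_CLASS7", "REAL_CLASS0",
             "REAL_CLASS0"), levels = activity_classes()), ids)
  tab <- suppressWarnings(distribution_table(m, cls))
  r <- group_ratios(tab, "SUPERIOR_CLASS7", "REAL_CLASS0")
  expect_equal(r$ratio[r$sub_id == "s1"], 1)       # 50% / 50%
  expect_equal(r$status[r$sub_id == "s2"], "undefined_high")
  expect_equal(r$ratio[r$sub_id == "s2"], Inf)
  expect_equal(r$status[r$sub_id == "s3"], "absent")
  expect_true(is.na(r$ratio[r$sub_id == "s3"]))
  # reciprocal identity where both directions are defined
  r_back <- group_ratios(tab, "REAL_CLASS0", "SUPERIOR_CLASS7")
  both <- r$status == "ok" & r_back$status == "ok"
  expect_true(all(abs(r$ratio[both] * r_back$ratio[both] - 1) < 1e-12))
  # count basis agrees up to the group-size factor (equal sizes here)
  rc <- group_ratios(tab, "SUPERIOR_CLASS7", "REAL_CLASS0", basis = "count")
  expect_equal(rc$ratio, r$ratio)
})

test_that("distribution export writes complete tidy tables", {
  g <- generate(small_synth_spec(), verify = "none")
  m <- suppressMessages(build_matrix(g$compounds, g$substructures))
  cl <- classify(g$compounds)
  tab <- suppressWarnings(distribution_table(m, cl))
  expect_equal(nrow(tab), ncol(m) * length(distribution_groups()))
  dir <- withr::local_tempdir()
  paths <- write_distribution(m, tab, dir)
  expect_true(all(file.exists(paths)))
  dense <- utils::read.csv(file.path(dir, "binary_matrix.csv"),
                           check.names = FALSE)
  expect_equal(dim(dense), c(nrow(m), ncol(m) + 1))
  expect_equal(colSums(dense[, -1]), colSums(m) + 0)
})
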
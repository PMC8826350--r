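# distribution table built directly from percentage vectors, bypassing
# chemistry: one substructure, given pct per group (group size 100)
fake_table <- function(pct) {
  groups <- distribution_groups()
  stopifnot(length(pct) == length(groups))
  data.frame(sub_id = "s", group = groups, n_group = 100L,
             n_hits = as.integer(pct), pct = pct,
             stringsAsFactors = FALSE)
}

pcts <- function(sup = 0, med = 0, semi7 = 0, weak = 0, vweak = 0,
                 semi0 = 0, real0 = 0, uncl = 0) {
  c(sup, med, semi7, weak, vweak, semi0, real0, uncl)
}

test_that("point scoring spans the score range at the extremes", {
  cfg <- rule_config()
  none <- score_substructure("s", fake_table(pcts()), cfg)
  expect_equal(none$inner, "0")
  expect_equal(none$outer, "0")
  max_inner <- score_substructure("s", fake_table(pcts(sup = 100)), cfg)
  expect_equal(max_inner$inner, "+++")
  expect_equal(max_inner$outer, "0")
  max_outer <- score_substructure("s", fake_table(pcts(semi7 = 100)), cfg)
  expect_equal(max_outer$outer, "+++")
  expect_equal(max_outer$inner, "0")
})

test_that("score engine is monotone in the positive-group percentages", {
  cfg <- rule_config()
  lv <- function(x) match(x, c("0", "+", "++", "+++"))
  base_other <- pcts(semi0 = 8, real0 = 4, uncl = 10)
  prev <- "0"
  for (p in c(0, 3, 6, 15, 25, 45, 60, 90)) {
    cur <- score_substructure(
      "s", fake_table(base_other + pcts(sup = p)), cfg)$inner
    expect_gte(lv(cur), lv(prev), label = paste("pct", p))
    prev <- cur
  }
})

test_that("landscape assignment has inner precedence and full coverage", {
  expect_equal(assign_landscape("+++", "0"), "SUPERIOR_INNER")
  expect_equal(assign_landscape("+++", "+++"), "SUPERIOR_INNER")
  expect_equal(assign_landscape("++", "++"), "INFERIOR_INNER")
  expect_equal(assign_landscape("0", "+++"), "SUPERIOR_OUTER")
  expect_equal(assign_landscape("0", "++"), "INFERIOR_OUTER")
  for (i in c("0", "+")) {
    for (o in c("0", "+")) {
      expect_equal(assign_landscape(i, o), "INTERMEDIATE")
    }
  }
  # total over the whole score lattice
  for (i in c("0", "+", "++", "+++")) {
    for (o in c("0", "+", "++", "+++")) {
      expect_true(assign_landscape(i, o) %in%
                    c("SUPERIOR_INNER", "INFERIOR_INNER", "SUPERIOR_OUTER",
                      "INFERIOR_OUTER", "INTERMEDIATE"))
    }
  }
})

test_that("intermediate refinement separates the critical sub-populations", {
  ids <- paste0("c", 1:10)
  cls <- stats::setNames(
    factor(c(rep("REAL_CLASS0", 3), rep("SEMI_CLASS0", 3),
             rep("UNCLASSIFIED_PAN", 2), rep("SUPERIOR_CLASS7", 2)),
           levels = activity_classes()), ids)
  m <- cbind(
    only_real0 = c(TRUE, TRUE, FALSE, rep(FALSE, 7)),
    nowhere = rep(FALSE, 10),
    semi0_not_uncl = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
                       FALSE, FALSE, FALSE),
    semi0_and_uncl = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                       FALSE, FALSE, FALSE),
    everywhere = rep(TRUE, 10)
  )
  rownames(m) <- ids
  expect_equal(refine_intermediate("only_real0", m, cls),
               "UNTOLERATED_NEGATIVE")
  expect_equal(refine_intermediate("nowhere", m, cls), "INCONCLUSIVE")
  expect_equal(refine_intermediate("semi0_not_uncl", m, cls),
               "TOLERATED_NEGATIVE")
  expect_equal(refine_intermediate("semi0_and_uncl", m, cls), "PLAIN")
  # present in every group at identical percentage: equal distribution
  expect_equal(refine_intermediate("everywhere", m, cls), "INCONCLUSIVE")
  expect_error(refine_intermediate("missing_sub", m, cls), "unknown")
})

test_that("full landscape analysis partitions the catalogue", {
  g <- generate(small_synth_spec(), verify = "none")
  m <- suppressMessages(build_matrix(g$compounds, g$substructures))
  cl <- classify(g$compounds)
  ls <- suppressWarnings(landscape_analysis(m, cl, g$substructures))
  cen <- landscape_census(ls)
  expect_equal(sum(cen$groups), nrow(g$substructures))
  expect_equal(sum(cen$subtypes), cen$groups[["INTERMEDIATE"]])
  # non-intermediate substructures carry no subtype
  expect_true(all((ls$group == "INTERMEDIATE") == (ls$subtype != "NONE")))
  # planted zero-hit pattern is inconclusive
  expect_equal(ls$subtype[ls$sub_id == "s_furan"], "INCONCLUSIVE")
  # planted Real-Class-0-only pattern is untolerated negative
  expect_equal(ls$subtype[ls$sub_id == "s_cf3"], "UNTOLERATED_NEGATIVE")
})

test_that("filter sets are disjoint and exclude plain intermediates", {
  g <- generate(small_synth_spec(), verify = "none")
  m <- suppressMessages(build_matrix(g$compounds, g$substructures))
  cl <- classify(g$compounds)
  ls <- suppressWarnings(landscape_analysis(m, cl, g$substructures))
  sets <- filter_sets(ls, g$substructures)
  ids <- unlist(lapply(sets, `[[`, "sub_id"))
  expect_equal(anyDuplicated(ids), 0)
  inter_plain <- ls$sub_id[ls$subtype %in% c("PLAIN", "INCONCLUSIVE")]
  expect_length(intersect(ids, inter_plain), 0)
})

test_that("rule configuration rejects non-monotone thresholds", {
  expect_error(rule_config(inner_strong = 10, inner_moderate = 20),
               "strong >= moderate")
  cfg <- rule_config(ratio_basis = "count")
  expect_equal(cfg$ratio_basis, "count")
})
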
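test_that("published worked-example profiles classify as expected", {
  # two validated weak pan inhibitors from the screening campaign
  expect_equal(classify_profile(33.1, 38.6, 15.9), "VERY_WEAK_PAN")
  expect_equal(classify_profile(25.6, 60.9, 12.4), "VERY_WEAK_PAN")
  # potent on one target, no inhibition on another: neither pan nor Class 0
  expect_equal(classify_profile(22.7, "n.i.", 7.89), "OTHER")
  expect_equal(classify_profile(4.9, 4.9, 4.9), "SUPERIOR_CLASS7")
  expect_equal(classify_profile(">200", ">200", ">200"), "REAL_CLASS0")
})

test_that("class boundaries follow the stated conventions", {
  cases <- list(
    # value triple, expected class
    list(c(5, 1, 1), "MEDIUM_CLASS7"),      # 5 is not < 5 but in [5,10)
    list(c(4.99, 4.99, 4.99), "SUPERIOR_CLASS7"),
    list(c(10, 1, 1), "SEMI_CLASS7"),       # 10 in [10,15]
    list(c(15, 15, 15), "SEMI_CLASS7"),     # <= 15 inclusive
    list(c(15.01, 1, 1), "UNCLASSIFIED_PAN"),
    list(c(20, 20, 5), "WEAK_PAN"),         # >= 20 inclusive
    list(c(19.99, 20, 5), "UNCLASSIFIED_PAN"),  # only one >= 20
    list(c(20, 20, 10), "VERY_WEAK_PAN"),   # third in [10,200)
    list(c(20, 20, 9.99), "WEAK_PAN"),
    list(c(199.9, 199.9, 199.9), "UNCLASSIFIED_PAN"),
    list(c(200, 1, 1), "OTHER"),            # measured 200 is not < 200
    list(c(12, ">200", ">200"), "SEMI_CLASS0"),
    list(c(12, 180, ">200"), "SEMI_CLASS0"),
    list(c(200, ">200", ">200"), "SEMI_CLASS0"),  # measured 200 in [10,200]
    list(c(9.9, ">200", ">200"), "OTHER"),  # potent target forbids Class 0
    list(c(">200", ">200", ">200"), "REAL_CLASS0"),
    list(c(201, ">200", ">200"), "REAL_CLASS0"),  # measured beyond 200
    list(c(">100", ">100", ">100"), "OTHER")      # censored below 200: unknown
  )
  for (cs in cases) {
    expect_equal(classify_profile(cs[[1]][1], cs[[1]][2], cs[[1]][3]),
                 cs[[2]],
                 info = paste(cs[[1]], collapse = "/"))
  }
})

test_that("classification is a total deterministic partition", {
  vals <- c("1", "5", "7.5", "10", "12.5", "15", "17", "20", "100", "199",
            ">200", "n.i.")
  grid <- expand.grid(a = vals, b = vals, c = vals,
                      stringsAsFactors = FALSE)
  cls <- mapply(classify_profile, grid$a, grid$b, grid$c)
  expect_true(all(cls %in% activity_classes()))
  # deterministic: a second pass gives identical labels
  cls2 <- mapply(classify_profile, grid$a, grid$b, grid$c)
  expect_identical(cls, cls2)
})

test_that("lowering all IC50s never demotes a Class 7 compound to a weak tier", {
  set.seed(901)
  weak_tiers <- c("WEAK_PAN", "VERY_WEAK_PAN", "SEMI_CLASS0", "REAL_CLASS0")
  n_class7 <- 0L
  for (i in 1:150) {
    # half the draws concentrate in the potent regime so Class 7 tiers are
    # actually exercised
    v <- if (i %% 2 == 0) stats::runif(3, 0.2, 12) else
      stats::runif(3, 0.2, 250)
    before <- classify_profile(v[1], v[2], v[3])
    if (before %in% c("SUPERIOR_CLASS7", "MEDIUM_CLASS7"))
      n_class7 <- n_class7 + 1L
    s <- stats::runif(1, 0.1, 0.95)
    w <- v * s
    after <- classify_profile(w[1], w[2], w[3])
    if (before %in% c("SUPERIOR_CLASS7", "MEDIUM_CLASS7")) {
      expect_false(after %in% weak_tiers,
                   info = paste(round(v, 2), collapse = "/"))
    }
  }
  expect_gt(n_class7, 10)  # the property was exercised
})

test_that("absent measurements force OTHER with a warning", {
  d <- make_profile_compounds(list(ok = c("1", "1", "1"),
                                   gap = c("1", "", "1")))
  expect_warning(cl <- classify(d), "absent")
  expect_equal(as.character(cl[["gap"]]), "OTHER")
  expect_equal(as.character(cl[["ok"]]), "SUPERIOR_CLASS7")
})

test_that("census identities hold", {
  expect_equal(class_census(factor(character(0),
                                   levels = activity_classes()))$n_total, 0)
  d <- make_profile_compounds(list(
    s1 = c(1, 1, 1), s2 = c(2, 2, 2),          # superior
    m1 = c(7, 1, 1),                            # medium
    w1 = c(20, 20, 5),                          # weak pan
    u1 = c(18, 18, 18),                         # unclassified pan
    c0 = c(">200", ">200", ">200"),             # real class 0
    sc = c(12, ">200", ">200"),                 # semi class 0
    ot = c(3, "n.i.", 3)))                      # other
  cen <- class_census(classify(d))
  expect_equal(cen$n_total, 8)
  expect_equal(sum(cen$counts), cen$n_total)
  expect_equal(cen$n_class7, 3)
  expect_equal(cen$n_classified_pan, 4)
  expect_equal(cen$n_pan, 5)
  expect_equal(cen$n_class0, 2)
  expect_equal(cen$n_classified_pan + cen$n_unclassified_pan +
                 cen$n_class0 + cen$counts[["OTHER"]], cen$n_total)
})
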
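test_that("two_by_two validates its cells", {
  t <- two_by_two(1, 0, 0, 0)
  expect_equal(t$n, 1)
  expect_error(two_by_two(-1, 2, 3, 4), class = "latentprev_validation_error")
  expect_error(two_by_two(1.5, 2, 3, 4), class = "latentprev_validation_error")
  expect_error(two_by_two(0, 0, 0, 0), class = "latentprev_validation_error")
})

test_that("margins invert to the study table when given exact counts", {
  t <- crosstab_from_margins(4157, p_m1 = 432, p_m2 = 577,
                             concordance = 0.194)
  expect_equal(c(t$a, t$b, t$c, t$d), c(164, 413, 268, 3312))
  expect_equal(t$n, 4157)
  # printed proportions identify the survey count only to rounding: the
  # nearest-count solution differs by one in b/d but reproduces every
  # printed value
  t2 <- crosstab_from_margins(4157, p_m1 = 0.104, p_m2 = 0.139,
                              concordance = 0.194)
  expect_equal(round((t2$a + t2$c) / t2$n, 3), 0.104)
  expect_equal(round((t2$a + t2$b) / t2$n, 3), 0.139)
  expect_equal(round(concordance(t2), 3), 0.194)
})

test_that("margin inversion handles degenerate concordance", {
  # perfect concordance with equal margins: all positives agree
  t <- crosstab_from_margins(100, p_m1 = 20, p_m2 = 20, concordance = 1)
  expect_equal(c(t$a, t$b, t$c), c(20, 0, 0))
  # zero concordance: no overlap
  t0 <- crosstab_from_margins(100, p_m1 = 20, p_m2 = 30, concordance = 0)
  expect_equal(c(t0$a, t0$b, t0$c), c(0, 30, 20))
  expect_error(crosstab_from_margins(100, p_m1 = 90, p_m2 = 90, concordance = 0),
               class = "latentprev_validation_error")
})

test_that("margin inversion round-trips random tables exactly", {
  set.seed(101)
  for (def in c("positive_agreement", "cohen_kappa")) {
    for (rep in 1:25) {
      cells <- as.vector(rmultinom(1, sample(200:5000, 1),
                                   c(0.05, 0.1, 0.08, 0.77)))
      if (cells[1] + cells[2] + cells[3] == 0 || cells[1] == 0) next
      t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
      back <- crosstab_from_margins(t$n, p_m1 = t$a + t$c, p_m2 = t$a + t$b,
                                    concordance = concordance(t, def),
                                    definition = def)
      expect_equal(c(back$a, back$b, back$c, back$d),
                   c(t$a, t$b, t$c, t$d))
    }
  }
})

test_that("prevalence reproduces the printed frequentist estimates", {
  t <- study_table()
  survey <- prevalence(t, "m2")
  expect_equal(round(100 * survey$estimate, 1), 13.9)
  expect_equal(round(100 * survey$lower, 1), 12.8)
  expect_equal(round(100 * survey$upper, 1), 14.9)
  admin <- prevalence(t, "m1")
  expect_equal(round(100 * admin$estimate, 1), 10.4)
  expect_equal(round(100 * admin$lower, 1), 9.5)
  expect_equal(round(100 * admin$upper, 1), 11.3)
  # degenerate: everyone positive
  all_pos <- prevalence(two_by_two(10, 0, 0, 0), "m1")
  expect_equal(all_pos$estimate, 1)
  expect_equal(all_pos$upper, 1)
})

test_that("Wald interval width scales as 1/sqrt(n)", {
  widths <- sapply(c(1, 4, 16), function(k) {
    t <- two_by_two(100 * k, 200 * k, 150 * k, 1550 * k)
    p <- prevalence(t, "m1")
    p$upper - p$lower
  })
  expect_equal(widths[1] / widths[2], 2, tolerance = 1e-10)
  expect_equal(widths[2] / widths[3], 2, tolerance = 1e-10)
})

test_that("concordance matches the printed value and its definitions behave", {
  t <- study_table()
  expect_equal(round(concordance(t), 3), 0.194)
  # kappa by direct arithmetic on the same table
  p_o <- (164 + 3312) / 4157
  p_e <- (577 * 432 + 3580 * 3725) / 4157^2
  expect_equal(concordance(t, "cohen_kappa"), (p_o - p_e) / (1 - p_e))
  expect_equal(round(concordance(t, "cohen_kappa"), 2), 0.23)
  # perfect agreement
  agree <- two_by_two(25, 0, 0, 75)
  expect_equal(concordance(agree), 1)
  expect_equal(concordance(agree, "cohen_kappa"), 1)
  # positive agreement ignores d
  t_d <- two_by_two(164, 413, 268, 9999)
  expect_equal(concordance(t_d), concordance(t))
  expect_error(concordance(two_by_two(0, 0, 0, 5)),
               class = "latentprev_validation_error")
})

test_that("crosstabs read from csv, json and yaml, cells or margins", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "t.csv")
  writeLines(c("a,b,c,d", "164,413,268,3312"), csv)
  expect_equal(read_crosstab(csv)$n, 4157)

  json <- file.path(dir, "t.json")
  jsonlite::write_json(list(a = 1, b = 0, c = 0, d = 0), json, auto_unbox = TRUE)
  expect_equal(read_crosstab(json)$n, 1)

  yml <- file.path(dir, "t.yaml")
  writeLines(c("n: 4157", "p_admin: 432", "p_survey: 577",
               "concordance: 0.194"), yml)
  t <- read_crosstab(yml)
  expect_equal(c(t$a, t$b, t$c, t$d), c(164, 413, 268, 3312))

  bad <- file.path(dir, "bad.csv")
  writeLines(c("a,b,c,d", "-1,2,3,4"), bad)
  expect_error(read_crosstab(bad), class = "latentprev_validation_error")
  expect_error(read_crosstab(file.path(dir, "missing.csv")),
               class = "latentprev_io_error")
  incomplete <- file.path(dir, "inc.json")
  jsonlite::write_json(list(a = 1, b = 2), incomplete, auto_unbox = TRUE)
  expect_error(read_crosstab(incomplete), class = "latentprev_validation_error")
})

test_that("descriptive_stats emits a tidy three-row table", {
  s <- descriptive_stats(study_table())
  expect_equal(nrow(s), 3)
  expect_named(s, c("statistic", "estimate", "lower", "upper"))
  expect_true(all(s$estimate >= 0 & s$estimate <= 1))
})
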
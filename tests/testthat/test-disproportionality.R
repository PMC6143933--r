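test_that("build_contingency fills cells under the XOR eligibility rule", {
  cohort <- mk_cohort(list(
    list(drugs = "D", reactions = "CASEPT"),
    list(drugs = "D", reactions = "CTRLPT"),
    list(drugs = "Z", reactions = "CASEPT"),
    list(drugs = "Z", reactions = "CTRLPT")
  ))
  t <- build_contingency(cohort, "D", "CasePT", "CtrlPT")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 1))
  expect_equal(t$n_both_excluded, 0)

  # a case listing BOTH events is excluded and counted
  cohort2 <- mk_cohort(list(
    list(drugs = "D", reactions = c("CASEPT", "CTRLPT")),
    list(drugs = "D", reactions = "CASEPT"),
    list(drugs = "Z", reactions = "CTRLPT")
  ))
  t2 <- build_contingency(cohort2, "D", "CASEPT", "CTRLPT")
  expect_equal(t2$n_both_excluded, 1)
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(1, 0, 0, 1))

  expect_error(build_contingency(cohort, "D", "SAME", "same"), "differ")
  expect_error(build_contingency(cohort, "D", "NOPE1", "NOPE2"), "eligible")
})

test_that("contingency cells equal brute-force enumeration on random cohorts", {
  set.seed(31)
  for (rep in 1:3) {
    specs <- lapply(1:120, function(i) {
      list(drugs = sample(c("D1", "D2", "D3"), sample(1:2, 1)),
           reactions = sample(c("CASEPT", "CTRLPT", "OTHER1", "OTHER2"),
                              sample(1:3, 1)))
    })
    cohort <- mk_cohort(specs)
    t <- build_contingency(cohort, "D1", "CASEPT", "CTRLPT")
    # oracle: loop over the spec list itself
    a <- b <- cc <- d <- both <- 0
    for (s in specs) {
      has_case <- "CASEPT" %in% toupper(s$reactions)
      has_ctrl <- "CTRLPT" %in% toupper(s$reactions)
      exp <- "D1" %in% toupper(s$drugs)
      if (has_case && has_ctrl) { both <- both + 1; next }
      if (has_case) { if (exp) a <- a + 1 else cc <- cc + 1 }
      if (has_ctrl) { if (exp) b <- b + 1 else d <- d + 1 }
    }
    expect_equal(c(t$a, t$b, t$c, t$d, t$n_both_excluded), c(a, b, cc, d, both))
  }
})

test_that("ror_closed_form matches hand-derived values", {
  # symmetry: uniform table
  r0 <- ror_closed_form(contingency_table(10, 10, 10, 10))
  expect_equal(r0$estimate, 1)
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  # ln 16 +/- 1.96 * sqrt(0.375), worked by hand
  r <- ror_closed_form(contingency_table(20, 5, 10, 40))
  expect_equal(r$estimate, 16)
  expect_equal(r$ci_low, exp(log(16) - 1.96 * sqrt(0.375)), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(16) + 1.96 * sqrt(0.375)), tolerance = 1e-12)
  expect_equal(round(r$ci_low, 2), 4.82)
  expect_equal(round(r$ci_high, 1), 53.1)
  expect_true(r$significant)

  # Haldane correction on a zero cell
  rc <- ror_closed_form(contingency_table(0, 5, 10, 40))
  expect_true(rc$corrected)
  expect_equal(rc$estimate, (0.5 * 40.5) / (5.5 * 10.5))
})

test_that("Wald estimates equal the geometric mean of their CI bounds", {
  set.seed(5)
  for (i in 1:20) {
    cells <- sample(1:60, 4, replace = TRUE)
    r <- ror_closed_form(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_equal(r$estimate, sqrt(r$ci_low * r$ci_high), tolerance = 1e-9)
  }
  # the published ondansetron interval is Wald-consistent
  expect_equal(round(ci_geometric_mean(1.59, 31.9), 2), 7.12)
})

test_that("logistic and closed-form ROR agree on all-positive tables", {
  set.seed(17)
  for (i in 1:25) {
    cells <- sample(1:80, 4, replace = TRUE)
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    lr <- ror_logistic(t)
    cf <- ror_closed_form(t)
    expect_equal(lr$estimate, cf$estimate, tolerance = 1e-6)
    # the SE inherits glm's IRLS stopping tolerance, so CI and p match a
    # little less tightly than the point estimate
    expect_equal(lr$ci_low, cf$ci_low, tolerance = 1e-4)
    expect_equal(lr$p_value, cf$p_value, tolerance = 1e-4)
    expect_false(lr$unstable)
  }
  # symmetric table: coefficient ~ 0
  expect_equal(ror_logistic(contingency_table(10, 10, 10, 10))$estimate, 1,
               tolerance = 1e-9)
  # zero cell: separation flag plus corrected closed form attached
  sep <- ror_logistic(contingency_table(0, 5, 10, 40))
  expect_true(sep$unstable)
  expect_true(sep$closed_form$corrected)
})

test_that("relabeling case and control inverts the estimate", {
  cohort <- mk_cohort(c(
    lapply(1:20, function(i) list(drugs = "D", reactions = "E1")),
    lapply(1:5, function(i) list(drugs = "D", reactions = "E2")),
    lapply(1:10, function(i) list(drugs = "Z", reactions = "E1")),
    lapply(1:40, function(i) list(drugs = "Z", reactions = "E2"))
  ))
  fwd <- ror_closed_form(build_contingency(cohort, "D", "E1", "E2"))
  rev <- ror_closed_form(build_contingency(cohort, "D", "E2", "E1"))
  expect_equal(fwd$estimate, 1 / rev$estimate, tolerance = 1e-12)
  expect_equal(fwd$ci_low, 1 / rev$ci_high, tolerance = 1e-12)
  expect_equal(fwd$ci_high, 1 / rev$ci_low, tolerance = 1e-12)
})

test_that("prr and rrr match their defining arithmetic", {
  # drug: 100 reports, 10 events; no-drug: 900 reports, 10 events -> PRR 9
  t <- contingency_table(10, 90, 10, 890)
  expect_equal(prr(t)$estimate, 9)
  # identical event rate in both strata -> PRR 1
  expect_equal(prr(contingency_table(5, 45, 20, 180))$estimate, 1)
  # RRR = a N / (n_drug n_event): 10*1000/(100*20) = 5
  expect_equal(rrr(contingency_table(10, 90, 10, 890))$estimate,
               10 * 1000 / (100 * 20))
  # independence -> RRR 1
  expect_equal(rrr(contingency_table(10, 90, 90, 810))$estimate, 1)
  # zero a -> corrected, flagged
  expect_true(rrr(contingency_table(0, 100, 10, 890))$corrected)
  expect_true(prr(contingency_table(0, 100, 10, 890))$corrected)

  # cohort route agrees with the cell route
  cohort <- mk_cohort(c(
    lapply(1:4, function(i) list(drugs = "D", reactions = "EV")),
    lapply(1:16, function(i) list(drugs = "D", reactions = "OTHER")),
    lapply(1:5, function(i) list(drugs = "Z", reactions = "EV")),
    lapply(1:75, function(i) list(drugs = "Z", reactions = "OTHER"))
  ))
  expect_equal(prr(cohort, "D", "EV")$estimate, (4 / 20) / (5 / 80))
  expect_equal(rrr(cohort, "D", "EV")$estimate, 4 * 100 / (20 * 9))
})

test_that("scan_drugs is antisymmetric and sorted", {
  cohort <- mk_cohort(c(
    lapply(1:20, function(i) list(drugs = "DRUGA", reactions = "E1")),
    lapply(1:5, function(i) list(drugs = "DRUGA", reactions = "E2")),
    lapply(1:10, function(i) list(drugs = "DRUGB", reactions = "E1")),
    lapply(1:40, function(i) list(drugs = "DRUGB", reactions = "E2"))
  ))
  res <- scan_drugs(cohort, "E1", "E2", c("DRUGA", "DRUGB"))
  expect_equal(res$drug, c("DRUGA", "DRUGB"))
  expect_equal(res$estimate, c(16, 1 / 16), tolerance = 1e-6)
  expect_error(scan_drugs(cohort, "E1", "E2", character(0)), "empty")
  # absent drugs are skipped with a message
  expect_message(res2 <- scan_drugs(cohort, "E1", "E2", c("DRUGA", "GHOST")),
                 "skipped")
  expect_equal(nrow(res2), 1)
})
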
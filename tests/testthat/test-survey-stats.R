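# Survey-level statistics: exact binomial rates, breakdowns, period tests.

fake_result <- function(id, verdict, channel = "internet", year = 2008,
                        type = "caviar") {
  structure(list(lot_id = id, label = parse_label("Sevruga"), channel = channel,
                 year = year, sample_type = type, verdict = verdict,
                 confirmation = "none", final = NULL,
                 markers_used = "cytb", n_eggs = 1L, n_haplotypes = 1L,
                 dloop_obtained = FALSE),
            class = "lot_result")
}

fake_survey <- function(n, m, channel_m = "internet", channel_ok = "in-store") {
  c(lapply(seq_len(m), function(i) fake_result(paste0("M", i), "mislabeled",
                                               channel = channel_m)),
    lapply(seq_len(n - m), function(i) fake_result(paste0("C", i), "consistent",
                                                   channel = channel_ok)))
}

test_that("rates and Clopper-Pearson intervals are exact", {
  s <- mislabeling_rate(fake_survey(90, 9))
  expect_equal(s$n_tested, 90)
  expect_equal(s$rate, 10)
  expect_equal(s$ci / 100, cp_interval_oracle(9, 90), tolerance = 1e-9)
  s0 <- mislabeling_rate(fake_survey(50, 0))
  expect_equal(s0$rate, 0)
  expect_equal(s0$ci[1], 0)
  # extraction failures, meat and unresolved lots leave the denominator
  res <- c(fake_survey(10, 1), list(fake_result("F", "extraction-failed"),
                                    fake_result("U", "unresolved"),
                                    fake_result("MT", "consistent", type = "meat")))
  expect_equal(mislabeling_rate(res)$n_tested, 10)
  expect_error(mislabeling_rate(list(fake_result("F", "extraction-failed"))),
               "no testable")
})

test_that("mixed lots count as mislabeled but are reported separately", {
  res <- c(fake_survey(10, 1), list(fake_result("X", "mixed")))
  s <- mislabeling_rate(res)
  expect_equal(s$n_mislabeled, 2)
  expect_equal(s$n_mixed, 1)
})

test_that("breakdowns partition the testable lots and reconcile", {
  res <- fake_survey(90, 9)
  bd <- survey_breakdown(res, "channel")
  expect_setequal(names(bd), c("in-store", "internet"))
  expect_equal(bd$internet$n_mislabeled, 9)
  expect_equal(bd$`in-store`$n_mislabeled, 0)
  tot <- attr(bd, "overall")
  expect_equal(sum(vapply(bd, `[[`, numeric(1), "n_tested")), tot$n_tested)
  expect_equal(sum(vapply(bd, `[[`, numeric(1), "n_mislabeled")),
               tot$n_mislabeled)
  one <- survey_breakdown(fake_survey(20, 2, channel_ok = "internet"), "channel")
  expect_equal(one$internet$rate, attr(one, "overall")$rate)
})

test_that("period comparison matches the hypergeometric oracle", {
  eq <- compare_periods(c(9, 90), c(9, 90))
  expect_equal(eq$difference, 0)
  expect_equal(eq$p_value, 1)
  cmp <- compare_periods(c(9, 90), c(18, 95))
  expect_equal(cmp$p_value, fisher_p_oracle(9, 90, 18, 95), tolerance = 1e-9)
  expect_lt(cmp$difference, 0)
  expect_true(cmp$ci[1] <= cmp$difference && cmp$difference <= cmp$ci[2])
  ext <- compare_periods(c(0, 10), c(10, 10))
  expect_equal(ext$difference, -100)
  expect_true(ext$p_value >= 0 && ext$p_value <= 1)
})

test_that("exact CI coverage at the survey's own design point", {
  # 400 binomial draws at p = 0.10, n = 90: the 95% CP interval should
  # cover the truth in at least ~93% of surveys
  set.seed(12345)
  covered <- 0
  for (i in 1:400) {
    x <- rbinom(1, 90, 0.10)
    ci <- cp_interval_oracle(x, 90)
    s <- mislabeling_rate(fake_survey(90, x))
    expect_equal(s$ci / 100, ci, tolerance = 1e-9)
    if (ci[1] <= 0.10 && 0.10 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / 400, 0.93)
})
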
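test_that("confusion partitions the cohort against truth", {
  toy <- tibble::tibble(
    truth = c("case", "case", "control", "control"),
    t = c("positive", "negative", "positive", "negative")
  )
  ct <- confusion(toy, "t")
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")], use.names = FALSE),
               rep(1L, 4))
  expect_equal(glance(ct)$n, nrow(toy))
  expect_error(confusion(toy, "nope"), "Unknown test")

  set.seed(1)
  big <- tibble::tibble(truth = sample(c("case", "control"), 100, TRUE),
                        t = sample(c("positive", "negative"), 100, TRUE))
  expect_equal(glance(confusion(big, "t"))$n, 100)
})

test_that("metrics compute exact fractions with half-up integer percents", {
  m <- metrics(contingency(tp = 111, fp = 25, fn = 51, tn = 29))
  got <- rlang::set_names(m$percent, m$metric)
  expect_equal(got[["sensitivity"]], 69)
  expect_equal(got[["specificity"]], 54)
  expect_equal(got[["ppv"]], 82)
  expect_equal(got[["npv"]], 36)
  expect_equal(got[["accuracy"]], 65)

  m2 <- metrics(contingency(1, 0, 0, 1))
  expect_true(all(m2$percent == 100))

  m3 <- metrics(contingency(tp = 93, fp = 42, fn = 33, tn = 43))
  got3 <- rlang::set_names(m3$percent, m3$metric)
  expect_equal(got3[["sensitivity"]], 74)
  expect_equal(got3[["specificity"]], 51)
  expect_equal(got3[["accuracy"]], 64)

  # zero denominator flags, does not throw
  m4 <- metrics(contingency(tp = 0, fp = 0, fn = 2, tn = 3))
  expect_false(m4$defined[m4$metric == "ppv"])
  expect_true(is.na(m4$percent[m4$metric == "ppv"]))

  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.345, 1), 2.3)
  expect_equal(round_half_up(2.35, 1), 2.4)
})

test_that("exact McNemar equals binomial enumeration for all b + c <= 30", {
  # independent oracle: explicit enumeration of the symmetric binomial
  enum_p <- function(b, cc) {
    n <- b + cc
    probs <- choose(n, 0:n) / 2^n
    k <- min(b, cc)
    min(1, 2 * sum(probs[seq_len(k + 1)]))
  }
  for (n in 1:30) {
    for (b in 0:n) {
      got <- mcnemar_test(c(b, n - b), method = "exact")$p_value
      expect_equal(got, enum_p(b, n - b), tolerance = 1e-12)
    }
  }
})

test_that("McNemar variants behave as documented", {
  sym <- mcnemar_test(c(5, 5), method = "exact")
  expect_equal(sym$p_value, 1)
  corr <- mcnemar_test(c(5, 5), method = "corrected")
  expect_lte(corr$statistic, 0.1)
  expect_gt(corr$p_value, 0.7)

  ext <- mcnemar_test(c(10, 0), method = "exact")
  expect_equal(ext$p_value, 2 * 0.5^10)

  big <- mcnemar_test(c(40, 20), method = "corrected")
  bige <- mcnemar_test(c(40, 20), method = "exact")
  expect_lt(abs(big$p_value - bige$p_value), 0.02)

  deg <- mcnemar_test(c(0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  # auto switches at b + c = 25
  expect_equal(mcnemar_test(c(10, 10))$method, "exact")
  expect_equal(mcnemar_test(c(20, 10))$method, "corrected")

  td <- tidy(mcnemar_test(c(3, 8)))
  expect_equal(td$b, 3)
  expect_s3_class(td, "tbl_df")
})

test_that("Fisher p-values equal hypergeometric enumeration on small tables", {
  fisher_enum <- function(a, b, cc, d) {
    m <- a + b; n <- cc + d; k <- a + cc
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(8)
  # all totals <= 12 exhaustively, plus random tables with margins <= 30
  small <- expand.grid(a = 0:4, b = 0:4, cc = 0:4, d = 0:4)
  small <- small[rowSums(small) > 0, ]
  for (i in seq_len(nrow(small))) {
    tb <- as.numeric(small[i, ])
    got <- stats::fisher.test(matrix(tb, 2, 2, byrow = TRUE))$p.value
    expect_equal(got, fisher_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
  for (i in 1:200) {
    tb <- as.numeric(sample(0:15, 4, replace = TRUE))
    if (sum(tb) == 0) next
    got <- categorical_test(tb, min_expected = Inf)  # force Fisher
    expect_equal(got$p_value, fisher_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
  }
})

test_that("categorical test switches between chi-square and Fisher", {
  flat <- categorical_test(c(5, 5, 5, 5))
  expect_equal(flat$p_value, 1)

  ext <- categorical_test(c(10, 0, 0, 10))
  expect_equal(ext$method, "fisher")
  expect_equal(ext$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  big <- categorical_test(c(50, 30, 20, 40))
  expect_equal(big$method, "chisq")
  # closed-form Pearson statistic
  a <- 50; b <- 30; cc <- 20; d <- 40; n <- a + b + cc + d
  stat <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(big$statistic, stat, tolerance = 1e-10)
  expect_equal(big$p_value, stats::pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(categorical_test(c(0, 0, 0, 0)), "Empty")
})

test_that("OR-combination is idempotent, monotone, and hits the published 83%", {
  co <- cohort_table2()
  same <- combine_tests_or(co, c("cgm", "cgm"), name = "cc")
  expect_equal(same$cc, co$cgm)

  comb <- combine_tests_or(co, c("cgm", "troponin_first"))
  m <- metrics(confusion(comb, "cgm_or_troponin_first"))
  sens_comb <- m$fraction[m$metric == "sensitivity"]
  for (t in c("cgm", "troponin_first")) {
    mt <- metrics(confusion(co, t))
    expect_gte(sens_comb, mt$fraction[mt$metric == "sensitivity"])
    expect_lte(m$fraction[m$metric == "specificity"],
               mt$fraction[mt$metric == "specificity"])
  }
  expect_equal(m$numerator[m$metric == "sensitivity"], 134)
  expect_equal(m$percent[m$metric == "sensitivity"], 83)

  # growing the test set never lowers sensitivity
  all3 <- combine_tests_or(co, c("cgm", "troponin_first", "ecg"), name = "k3")
  m3 <- metrics(confusion(all3, "k3"))
  expect_gte(m3$fraction[m3$metric == "sensitivity"], sens_comb)

  expect_error(combine_tests_or(co, character(0)), "Empty")
  expect_error(combine_tests_or(co, "nope"), "Unknown")
})

test_that("screening yield reproduces the gatekeeper-negative arithmetic", {
  co <- cohort_table2()
  y <- screening_yield(co, "cgm", c("ecg", "troponin_serial"))
  expect_equal(y$n_subgroup, 106)
  expect_equal(y$additional_tp, 42)
  expect_equal(y$fp, 17)
  expect_equal(y$nnt, 2.5)
  expect_equal(y$nnh, 6.2)

  # degenerate cases flag rather than throw
  none <- tibble::tibble(truth = c("case", "control"),
                         gate = c("negative", "negative"),
                         t = c("negative", "negative"))
  y0 <- screening_yield(none, "t", "gate")
  expect_false(y0$nnt_defined)
  expect_false(y0$nnh_defined)
  expect_true(is.na(y0$nnt))
})

test_that("cohort-level evaluation recovers generating characteristics", {
  sp <- cohort_spec_table2(n_cases = 20000, n_controls = 20000, seed = 31)
  co <- synth_cohort(sp)
  ev <- evaluate_cohort(co, sp$tests$test)
  for (i in seq_len(nrow(sp$tests))) {
    t <- sp$tests$test[i]
    sens <- ev$numerator[ev$metric == "sensitivity" & ev$test == t] /
      ev$denominator[ev$metric == "sensitivity" & ev$test == t]
    spc <- ev$numerator[ev$metric == "specificity" & ev$test == t] /
      ev$denominator[ev$metric == "specificity" & ev$test == t]
    expect_lt(abs(sens - sp$tests$sensitivity[i]), 0.01)
    expect_lt(abs(spc - sp$tests$specificity[i]), 0.01)
  }
})
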
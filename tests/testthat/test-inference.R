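test_that("cooperator frequency is one minus the resistant fraction", {
  # the early-coevolution reading: 140 resistant of 200 is a 3:7 ratio
  est <- estimate_frequency(140, n_colonies = 200)
  expect_equal(est$p_hat, 0.30)
  expect_true(est$ci_low <= est$p_hat && est$p_hat <= est$ci_high)

  # boundary: no resistant colonies
  est <- estimate_frequency(0, n_colonies = 200)
  expect_equal(est$p_hat, 1)
  expect_equal(est$ci_high, 1)
  expect_lt(est$ci_low, 1)

  # Wilson interval is symmetric about 1/2 at an even split
  est <- estimate_frequency(100, n_colonies = 200)
  expect_equal(est$p_hat, 0.5)
  expect_equal(est$ci_low + est$ci_high, 1, tolerance = 1e-12)

  expect_error(estimate_frequency(201, n_colonies = 200),
               class = "privcoop_domain_error")
  expect_error(estimate_frequency(-1, n_colonies = 200),
               class = "privcoop_domain_error")
})

test_that("the data-frame method appends estimate columns", {
  ds <- generate_coevolution_dataset(
    coevolution_design(n_lines = 2, truth = ref_params(), master_seed = 1))
  est <- estimate_frequency(ds)
  expect_true(all(c("p_hat", "ci_low", "ci_high") %in% names(est)))
  expect_equal(est$p_hat, 1 - ds$n_resistant / ds$n_colonies)
  expect_true(all(est$ci_low <= est$p_hat & est$p_hat <= est$ci_high))
})

test_that("Wilson bounds match the score-test interval of prop.test", {
  cases <- expand.grid(k = c(0, 1, 17, 60, 100, 140, 199, 200),
                       n = c(50, 200, 800))
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    est <- estimate_frequency(n - k, n_colonies = n)  # k cooperator colonies
    ref <- prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(est$ci_low, ref[1], tolerance = 1e-10)
    expect_equal(est$ci_high, ref[2], tolerance = 1e-10)
  }
})

test_that("line summaries average the replicate estimates per generation", {
  d <- coevolution_design(n_lines = 1, truth = ref_params(), master_seed = 2)
  ds <- generate_coevolution_dataset(d)
  s <- summarize_lines(ds)
  expect_equal(s$mean_p, 1 - ds$n_resistant / ds$n_colonies)
  expect_equal(s$sd_p, rep(0, nrow(s)))
  expect_equal(s$n_lines, rep(1L, nrow(s)))

  # six identical lines have zero dispersion
  six <- do.call(rbind, lapply(1:6, function(i) {
    transform(ds, line_id = sprintf("line_%d", i))
  }))
  s6 <- summarize_lines(six)
  expect_equal(s6$sd_p, rep(0, nrow(s6)))
  expect_equal(s6$n_lines, rep(6L, nrow(s6)))

  expect_error(summarize_lines(data.frame()),
               class = "privcoop_domain_error")
})

test_that("across-line dispersion matches binomial sampling theory", {
  # neutral lines at x_true = 0.5, n = 200: per-line SD sqrt(0.25 / 200)
  sds <- vapply(1:200, function(s) {
    d <- coevolution_design(n_lines = 6,
                            truth = coop_params(alpha = 0, C = 0),
                            master_seed = s)
    summarize_lines(generate_coevolution_dataset(d))$sd_p[1]
  }, numeric(1))
  sigma <- sqrt(0.25 / 200)
  c4 <- sqrt(2 / 5) * gamma(3) / gamma(2.5)  # E[sd]/sigma at n = 6
  mc_se <- sd(sds) / sqrt(length(sds))
  expect_lt(abs(mean(sds) - c4 * sigma), 3 * mc_se)
})

test_that("group comparisons reproduce the classical t statistic", {
  ident <- compare_groups(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(ident$t_statistic, 0)
  expect_equal(ident$p_value, 1)

  # hand computation of the pooled-variance formula
  a <- c(0.1, 0.2, 0.3); b <- c(0.4, 0.5, 0.6)
  cmp <- compare_groups(a, b)
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(cmp$t_statistic, -3.674, tolerance = 1e-3)
  expect_equal(cmp$degrees_of_freedom, 4)
  expect_equal(cmp$p_value, 2 * pt(t_hand, df = 4), tolerance = 1e-10)
  expect_equal(cmp$mean_difference, -0.3)

  # paired variant on the same values
  cmp_p <- compare_groups(a, b, paired = TRUE)
  expect_equal(cmp_p$degrees_of_freedom, 2)
  expect_equal(cmp_p$mean_difference, -0.3)

  # Welch df falls below the pooled df under unequal variances
  set.seed(8)
  aa <- rnorm(6, sd = 0.01); bb <- rnorm(6, sd = 0.2)
  expect_lt(compare_groups(aa, bb, welch = TRUE)$degrees_of_freedom,
            compare_groups(aa, bb)$degrees_of_freedom)

  # constant equal groups are a no-signal convention, not an error
  flat <- compare_groups(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(flat$t_statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(compare_groups(0.5, c(0.4, 0.6)),
               class = "privcoop_domain_error")
  expect_error(compare_groups(c(0.1, 0.2, 0.3), c(0.4, 0.5), paired = TRUE),
               class = "privcoop_domain_error")
})

test_that("strong selection is detected between first and last assays", {
  # start-vs-end comparison rejects neutrality in nearly all replicates
  hits <- vapply(1:100, function(s) {
    d <- coevolution_design(n_lines = 6, truth = ref_params(),
                            master_seed = s)
    est <- estimate_frequency(generate_coevolution_dataset(d))
    g0 <- min(est$generation); gT <- max(est$generation)
    compare_groups(est$p_hat[est$generation == gT],
                   est$p_hat[est$generation == g0])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
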
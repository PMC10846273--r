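test_that("resource shares follow the privatization split", {
  # no privatization: everyone draws from the same pool
  s <- resource_shares(coop_params(alpha = 0, r = 1, C = 0.1), x = 0.5)
  expect_equal(s$R_co, 0.5)
  expect_equal(s$R_ch, 0.5)

  # no cooperators in the pool: only the private share remains
  s <- resource_shares(coop_params(alpha = 0.3, r = 2, C = 0.1), x = 0)
  expect_equal(s$R_co, 0.6)
  expect_equal(s$R_ch, 0)

  # direct substitution
  s <- resource_shares(coop_params(alpha = 0.2, r = 1, C = 0.1), x = 0.5)
  expect_equal(s$R_co, 0.6)
  expect_equal(s$R_ch, 0.4)
})

test_that("cooperator share exceeds cheater share by exactly alpha * r", {
  for (p in random_params(25, seed = 11)) {
    x <- seq(0, 1, length.out = 41)
    s <- resource_shares(p, x)
    expect_true(all(s$R_co >= s$R_ch))
    expect_true(all(s$R_ch >= 0))
    expect_equal(s$R_co - s$R_ch, rep(p$alpha * p$r, length(x)),
                 tolerance = 1e-14)
  }
})

test_that("fitness applies Monod saturation and charges only cooperators", {
  p <- coop_params(alpha = 0.2, r = 1, C = 0.1, fmax = 1, Km = 1)

  # no resource, no cheater growth
  f <- fitness(tibble::tibble(R_co = 0.5, R_ch = 0), p)
  expect_equal(f$f_ch, 0)

  # equal shares differ only by the cost
  f <- fitness(tibble::tibble(R_co = c(0.3, 1.7), R_ch = c(0.3, 1.7)), p)
  expect_equal(f$f_co, f$f_ch - p$C)

  # hand evaluation: 1 * 1 / (1 + 1) - 0.1
  f <- fitness(tibble::tibble(R_co = 1, R_ch = 0), p)
  expect_equal(f$f_co, 0.4)

  expect_error(fitness(tibble::tibble(R_co = -0.1, R_ch = 0), p),
               class = "privcoop_domain_error")
})

test_that("fitness gap reduces to the cost when nothing is privatized", {
  p <- coop_params(alpha = 0, r = 1, C = 0.1)
  expect_equal(fitness_gap(p, c(0, 0.25, 0.5, 1)), rep(-0.1, 4))

  # privatization with no cost always favors cooperators
  expect_gt(fitness_gap(coop_params(alpha = 0.2, r = 1, C = 0), 0.5), 0)

  # hand evaluation at x = 0: 0.2 / 1.2 - 0.1
  expect_equal(fitness_gap(ref_params(), 0), 0.2 / 1.2 - 0.1,
               tolerance = 1e-14)

  # matches the independent formula everywhere
  x <- seq(0, 1, length.out = 101)
  for (p in random_params(10, seed = 21)) {
    expect_equal(fitness_gap(p, x),
                 oracle_gap(p$alpha, p$r, p$fmax, p$Km, p$C, x),
                 tolerance = 1e-14)
  }
})

test_that("fitness gap decreases strictly in cooperator frequency", {
  x <- seq(0, 1, length.out = 1000)
  for (p in random_params(100, seed = 31)) {
    expect_true(all(diff(fitness_gap(p, x)) < 0))
  }
})

test_that("coexistence solver agrees with a brute-force grid scan", {
  for (p in random_params(30, seed = 41)) {
    s <- solve_coexistence(p)
    expect_true(s$x_star >= 0 && s$x_star <= 1)
    expect_lt(abs(s$x_star - oracle_grid_root(p)), 1e-6)
    if (s$status == "interior") expect_lt(s$residual, 1e-8)
  }
})

test_that("boundary clamping encodes competitive exclusion and fixation", {
  # no privatization but a positive cost: cheaters exclude cooperators
  s <- solve_coexistence(coop_params(alpha = 0, C = 0.1))
  expect_identical(s$x_star, 0)
  expect_identical(s$status, "clamped_low")

  # free cooperation with a private share: cooperators fix
  s <- solve_coexistence(coop_params(alpha = 0.2, r = 1, C = 0))
  expect_identical(s$x_star, 1)
  expect_identical(s$status, "clamped_high")
})

test_that("reference parameter set has the known interior equilibrium", {
  s <- solve_coexistence(ref_params())
  expect_identical(s$status, "interior")
  # frozen from the 1e-6-step grid-scan oracle
  expect_equal(s$x_star, 0.3971809, tolerance = 1e-6)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$x_star, s$x_star)
  expect_equal(td$alpha, 0.2)
})

test_that("sweep grid matches cell-wise solves and is monotone in alpha", {
  base <- coop_params(C = 0.1)

  # alpha = 0 with a positive cost: a whole row of exclusions
  sw <- sweep_alpha_r(base, alphas = 0, rs = c(0.5, 1, 2))
  expect_equal(sw$x_star, rep(0, 3))
  expect_equal(sw$status, rep("clamped_low", 3))

  # a single cell reproduces the dedicated solver
  sw <- sweep_alpha_r(base, alphas = 0.2, rs = 1)
  expect_equal(sw$x_star, solve_coexistence(ref_params())$x_star,
               tolerance = 1e-12)

  # three independent solves, strictly increasing in alpha
  sw <- sweep_alpha_r(base, alphas = c(0.1, 0.2, 0.4), rs = 1)
  expect_equal(nrow(sw), 3L)
  expect_true(all(diff(sw$x_star) > 0))

  # grid shape and monotone columns on a larger grid
  alphas <- seq(0.05, 0.8, by = 0.05)
  rs <- c(0.5, 1, 2)
  sw <- sweep_alpha_r(base, alphas, rs)
  expect_equal(nrow(sw), length(alphas) * length(rs))
  expect_true(all(sw$x_star >= 0 & sw$x_star <= 1))
  for (rv in rs) {
    expect_true(all(diff(sw$x_star[sw$r == rv]) >= 0))
  }
})

test_that("invalid inputs raise domain errors", {
  expect_error(coop_params(alpha = 1.2), class = "privcoop_domain_error")
  expect_error(coop_params(alpha = -0.1), class = "privcoop_domain_error")
  expect_error(coop_params(r = -1), class = "privcoop_domain_error")
  expect_error(coop_params(Km = 0), class = "privcoop_domain_error")
  expect_error(coop_params(fmax = 0), class = "privcoop_domain_error")
  expect_error(resource_shares(ref_params(), x = 1.5),
               class = "privcoop_domain_error")
  expect_error(fitness_gap(ref_params(), x = -0.2),
               class = "privcoop_domain_error")
  expect_error(solve_coexistence(ref_params(), tol = 0),
               class = "privcoop_domain_error")
  expect_error(sweep_alpha_r(ref_params(), numeric(0), 1),
               class = "privcoop_domain_error")
  expect_error(sweep_alpha_r(ref_params(), 0.2, -1),
               class = "privcoop_domain_error")
})
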
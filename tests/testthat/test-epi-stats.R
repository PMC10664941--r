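clean_fixture <- function(n = 10) {
  data.frame(case_id = seq_len(n), hour = rep(10L, n), age = rep(20L, n),
             syndrome = rep("mild_swelling", n),
             antivenom = rep(TRUE, n), vials = rep(3L, n))
}

test_that("validate_registry accepts clean rows and rejects violations", {
  v <- validate_registry(clean_fixture())
  expect_equal(v$n_accepted, 10L)
  expect_equal(v$n_rejected, 0L)

  bad <- clean_fixture(3)
  bad$hour[1] <- 25L
  bad$antivenom[2] <- FALSE            # vials without antivenom
  bad$syndrome[3] <- "spontaneous combustion"
  v2 <- validate_registry(bad)
  expect_equal(v2$n_rejected, 3L)
  expect_true("hour out of range" %in% v2$rejected$reason)
  expect_true("vials recorded without antivenom" %in% v2$rejected$reason)

  expect_error(validate_registry("no/such/file.csv"), "cannot read")
})

test_that("tabulate_cases rounds percentages and conserves counts", {
  cases <- data.frame(sex = rep(c("male", "female"), c(511, 421)))
  tt <- tabulate_cases(cases, "sex", digits = 0)
  expect_equal(tt$pct[tt$category == "male"], 55)
  expect_equal(sum(tt$n), 932)

  one <- tabulate_cases(data.frame(sex = "male"), "sex")
  expect_equal(one$pct, 100)

  set.seed(50)
  r <- data.frame(month = sample(month.abb, 500, TRUE))
  tm <- tabulate_cases(r, "month", digits = 4)
  expect_equal(sum(tm$n), 500)
  expect_lt(abs(sum(tm$pct) - 100), 0.01)
  expect_error(tabulate_cases(r, "shoe_size"), "unknown dimension")
})

test_that("annual_average divides by the period", {
  expect_equal(annual_average(932, 2), 466)
  expect_equal(annual_average(0, 3), 0)
  expect_equal(annual_average(10, 0.5), 20)
  expect_error(annual_average(10, 0), "positive")
})

test_that("relative_risk matches the closed-form CI oracle", {
  rr <- relative_risk(10, 100, 5, 100)
  expect_equal(rr$rr, 2)
  # direct evaluation of the CI formula:
  # se = sqrt(1/10 - 1/100 + 1/5 - 1/100) = sqrt(0.28)
  se <- sqrt(1 / 10 - 1 / 100 + 1 / 5 - 1 / 100)
  expect_equal(rr$lower, exp(log(2) - 1.96 * se))
  expect_equal(rr$upper, exp(log(2) + 1.96 * se))
  expect_equal(round(rr$lower, 3), 0.709)
  expect_equal(round(rr$upper, 2), 5.64)

  eq <- relative_risk(7, 70, 9, 90)
  expect_equal(eq$rr, 1)
  expect_true(eq$lower < 1 && eq$upper > 1)

  # RR(a,b) = 1 / RR(b,a)
  ab <- relative_risk(12, 200, 30, 500)
  ba <- relative_risk(30, 500, 12, 200)
  expect_equal(ab$rr, 1 / ba$rr)
  z <- relative_risk(0, 50, 5, 50)
  expect_false(z$ci_defined)
})

test_that("chi-squared and Cramer's V match the expansion oracle", {
  perfect <- chi2_cramers_v(rbind(c(10, 0), c(0, 10)))
  expect_equal(perfect$chi2, 20)
  expect_equal(perfect$cramers_v, 1)
  indep <- chi2_cramers_v(rbind(c(5, 5), c(5, 5)))
  expect_equal(indep$chi2, 0)
  expect_equal(indep$cramers_v, 0)

  set.seed(51)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  got <- chi2_cramers_v(tab)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  chi2_oracle <- 0
  for (i in 1:3) for (j in 1:4)
    chi2_oracle <- chi2_oracle + (tab[i, j] - expd[i, j])^2 / expd[i, j]
  expect_equal(got$chi2, chi2_oracle)
  expect_equal(got$chi2,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(got$df, 6)
  expect_equal(got$cramers_v, sqrt(chi2_oracle / (n * 2)))
  # permutation invariance of V
  got2 <- chi2_cramers_v(tab[c(3, 1, 2), c(2, 4, 1, 3)])
  expect_equal(got2$cramers_v, got$cramers_v)
  expect_error(chi2_cramers_v(matrix(c(1, 2), 1, 2)), "2x2")
  expect_error(chi2_cramers_v(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("poisson fit reproduces the two-group closed form and glm", {
  # two elevation groups: exp(beta) equals the group rate ratio exactly
  elev <- rep(c(200, 300), each = 20)
  pop <- rep(1000, 40)
  set.seed(52)
  counts <- c(rpois(20, 8), rpois(20, 5))
  fit <- poisson_elevation_fit(counts, elev, pop)
  r1 <- sum(counts[1:20]) / sum(pop[1:20])
  r2 <- sum(counts[21:40]) / sum(pop[21:40])
  expect_equal(exp(fit$coef_per_100m), r2 / r1, tolerance = 1e-8)

  # glm as an independent oracle on a non-saturated design
  set.seed(53)
  elev2 <- runif(60, 100, 1400)
  pop2 <- runif(60, 500, 5000)
  mu <- pop2 * 5e-4 * exp(-0.04 * elev2 / 100)
  counts2 <- rpois(60, mu)
  fit2 <- poisson_elevation_fit(counts2, elev2, pop2)
  g <- glm(counts2 ~ I(elev2 / 100) + offset(log(pop2)), family = poisson)
  expect_equal(fit2$coef_per_100m, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(fit2$se, unname(sqrt(diag(vcov(g)))[2]), tolerance = 1e-4)
  expect_equal(fit2$percent_change_per_100m,
               100 * (1 - exp(fit2$coef_per_100m)))
  expect_error(poisson_elevation_fit(1:5, 1:5, 1:5), "at least 10")
})

test_that("null elevation effect is covered by 2 SE in ~95% of replicates", {
  set.seed(54)
  cover <- replicate(100, {
    elev <- runif(50, 100, 1400)
    pop <- runif(50, 500, 5000)
    counts <- rpois(50, pop * 5e-4)     # beta = 0
    f <- poisson_elevation_fit(counts, elev, pop)
    abs(f$coef_per_100m) < 2 * f$se
  })
  # nominal coverage 95.4%; allow Monte-Carlo slack
  expect_gte(mean(cover), 0.90)
})
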
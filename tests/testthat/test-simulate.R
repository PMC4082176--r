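test_that("simulation is deterministic under a seed and degenerate when silent", {
  m <- suicide_model(Q0 = 5e4, initial_ill = 1000)
  a <- simulate(m, seed = 99, years = 30)
  b <- simulate(m, seed = 99, years = 30)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate(m, seed = 100, years = 30)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  # all-zero probabilities: nothing ever happens
  p0 <- validate_parameters(setNames(rep(0, 6),
                                     c("p21","p12","p31","p32","p41","p42")))
  tal0 <- simulate(suicide_model(p0, Q0 = 1e4, initial_ill = 100),
                   seed = 1, years = 20)
  ev <- c("healthy_to_ill", "healthy_to_death_other", "healthy_to_suicide",
          "ill_to_recovered", "ill_to_death_other", "ill_to_suicide")
  expect_true(all(tal0[, ev] == 0))
  expect_true(all(tal0$healthy_start == 9900))
  expect_true(all(tal0$ill_start == 100))
})

test_that("every simulated year conserves the population and replaces deaths", {
  m <- suicide_model(Q0 = 2e5, initial_ill = 4286)
  tal <- simulate(m, seed = 3, years = 80)
  # living at the start of each year is exactly Q0 (deaths already replaced)
  expect_true(all(tal$healthy_start + tal$ill_start == m$Q0))
  deaths <- tal$healthy_to_death_other + tal$healthy_to_suicide +
    tal$ill_to_death_other + tal$ill_to_suicide
  # living at the end of each year plus that year's deaths is Q0
  expect_true(all(tal$healthy_start + tal$ill_start == m$Q0))
  # next year's replacements equal this year's deaths
  expect_equal(tal$replacements[-1], deaths[-nrow(tal)])
  expect_equal(tal$replacements[1], 0)
  # events from a compartment never exceed its start count
  expect_true(all(tal$healthy_to_ill + tal$healthy_to_death_other +
                    tal$healthy_to_suicide <= tal$healthy_start))
  expect_true(all(tal$ill_to_recovered + tal$ill_to_death_other +
                    tal$ill_to_suicide <= tal$ill_start))
})

test_that("first simulated year reproduces the expected incidence", {
  # from 6.85 million healthy, ~19,591 new psychiatric cases are expected;
  # the draw must fall within 3 binomial standard deviations
  m <- hk_model()
  tal <- simulate(m, seed = 2026, years = 1)
  expected <- 0.00286 * 6850000
  sd3 <- 3 * sqrt(6850000 * 0.00286 * (1 - 0.00286))
  expect_lt(abs(tal$healthy_to_ill[1] - expected), sd3)
  expect_equal(tal$healthy_start[1], 6850000)
})

test_that("long-run ill share matches the stationary fraction", {
  m <- hk_model()
  tal <- simulate(m, seed = 5, years = 200)
  keep <- tal$year > 50   # burn-in while the transient decays
  share <- mean(tal$ill_start[keep] / m$Q0)
  expect_lt(abs(share - 0.0338), 0.001)
  # suicide flow likewise tracks its stationary value (~16.5 per 100k)
  zrate <- mean((tal$healthy_to_suicide + tal$ill_to_suicide)[keep]) / m$Q0
  expect_lt(abs(zrate * 1e5 - 16.5), 1)
})

test_that("transition probabilities are recovered from simulated tallies", {
  truth <- coef(hk_model())
  m <- suicide_model(Q0 = 1e6, initial_ill = 21429)
  fit <- estimate_transitions(simulate(m, seed = 17, years = 500))
  for (nm in names(truth)) {
    expect_lt(abs(coef(fit)[[nm]] - truth[[nm]]), 4 * fit$se[[nm]])
  }
  # and the recovered parameters predict the observed suicide share
  eq_hat <- equilibrium(fit$estimates, Q0 = 1)
  eq_true <- equilibrium(hk_model())
  expect_lt(abs(eq_hat$fractions[["z"]] - eq_true$fractions[["z"]]),
            0.1 * eq_true$fractions[["z"]])
})

test_that("2 SE intervals cover the truth at roughly nominal rate", {
  truth <- coef(hk_model())
  m <- suicide_model(Q0 = 1e5, initial_ill = 2143)
  set.seed(31)
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    fit <- estimate_transitions(simulate(m, years = 100))
    ci <- confint(fit, level = 0.9545)
    for (nm in names(truth)) {
      total <- total + 1L
      if (truth[[nm]] >= ci[nm, "lower"] && truth[[nm]] <= ci[nm, "upper"])
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.88)
})

test_that("estimation handles edge cases as errors, not zeros", {
  k_over_m <- data.frame(
    year = 1:3, healthy_start = 100, ill_start = 50,
    healthy_to_ill = 10, healthy_to_death_other = 1, healthy_to_suicide = 0,
    ill_to_recovered = 5, ill_to_death_other = 1, ill_to_suicide = 0,
    replacements = 0)
  fit <- estimate_transitions(k_over_m)
  expect_equal(coef(fit)[["p21"]], 10 / 100)   # constant ratio k/m
  expect_equal(coef(fit)[["p12"]], 5 / 50)
  no_ill <- k_over_m
  no_ill$ill_start <- 0
  expect_error(estimate_transitions(no_ill), "zero exposure")
  expect_error(estimate_transitions(k_over_m, burn_in = 3), "no years")
})

test_that("Pearson residuals are standardized under the true model", {
  m <- suicide_model(Q0 = 5e5, initial_ill = 10714)
  tal <- simulate(m, seed = 41, years = 150)
  r <- residuals(tal, params = m$params)
  vals <- unlist(r[, -1])
  expect_lt(abs(mean(vals)), 0.2)
  expect_gt(sd(vals), 0.7)
  expect_lt(sd(vals), 1.3)
})
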
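test_that("closed form gives the published Hong Kong stationary state", {
  eq <- equilibrium(hk_model())
  expect_equal(round(eq$fractions[["w"]], 3), 0.960)
  expect_equal(round(eq$fractions[["x"]], 4), 0.0338)
  expect_equal(round(eq$fractions[["y"]], 5), 0.00616)
  expect_equal(round(eq$fractions[["z"]], 6), 0.000165)
  expect_equal(sum(eq$fractions), 1, tolerance = 1e-12)
  expect_equal(eq$R,
               (1 + 0.006 + 0.0000834) * 0.0812 + 0.00286 * (1 + 0.0145))
})

test_that("stationary state is a fixed point of the replacement step", {
  set.seed(7)
  for (i in 1:50) {
    p <- random_params()
    Q0 <- 1e6
    eq <- equilibrium(p, Q0 = Q0)
    s <- population_state(eq$counts[["w"]], eq$counts[["x"]],
                          eq$counts[["y"]], eq$counts[["z"]])
    s1 <- step_population(s, p)
    expect_lt(max(abs(as.numeric(s1) - as.numeric(s))), 1e-9 * Q0)
  }
})

test_that("degenerate and boundary parameter sets behave as specified", {
  # no-death two-state chain: classic recovery/incidence balance
  p <- transition_params(p31 = 0, p32 = 0, p41 = 0, p42 = 0)
  eq <- equilibrium(p, Q0 = 1)
  expect_equal(eq$fractions[["w"]], 0.0667 / (0.0667 + 0.00286))
  expect_equal(eq$fractions[["x"]], 0.00286 / (0.0667 + 0.00286))
  expect_equal(eq$fractions[["y"]], 0)
  expect_equal(eq$fractions[["z"]], 0)
  # nobody ever becomes ill -> empty ill compartment
  eq0 <- equilibrium(transition_params(p21 = 0), Q0 = 1)
  expect_equal(eq0$fractions[["x"]], 0)
  # absorbing ill state: the closed form is indeterminate
  expect_error(
    equilibrium(transition_params(p12 = 0, p32 = 0, p42 = 0), Q0 = 1),
    "degenerate chain")
})

test_that("power iteration agrees with the closed form (HK scenario)", {
  m <- hk_model()
  it <- iterate_to_equilibrium(m, tol = 1e-12)
  eq <- equilibrium(m)
  expect_equal(it$fractions, eq$fractions, tolerance = 1e-10)
  # starting at the fixed point converges immediately
  eqs <- population_state(eq$counts[["w"]], eq$counts[["x"]],
                          eq$counts[["y"]], eq$counts[["z"]])
  expect_equal(iterate_to_equilibrium(m, init = eqs)$years, 1L)
})

test_that("power iteration matches the closed form on random chains", {
  set.seed(11)
  for (i in 1:1000) {
    p <- random_params()
    m <- suicide_model(p, Q0 = 1e6, initial_ill = 0)
    it <- iterate_to_equilibrium(m, tol = 1e-10)
    eq <- equilibrium(m)
    expect_lt(max(abs(it$fractions - eq$fractions)), 1e-9)
  }
})

test_that("iteration failure to converge is an error reporting the residual", {
  expect_error(iterate_to_equilibrium(hk_model(), max_years = 3),
               "no convergence after 3 years.*residual")
  expect_error(iterate_to_equilibrium(hk_model(), tol = -1), "tol must be > 0")
})

test_that("the ill share rises monotonically from 2.14% and stabilizes", {
  m <- hk_model()
  it <- iterate_to_equilibrium(m, keep_trajectory = TRUE)
  share <- 100 * it$trajectory$x / m$Q0
  expect_equal(share[1], 100 * 150000 / 7e6)  # 2.142857...
  expect_equal(round(share[1], 2), 2.14)
  expect_true(all(diff(share) > -1e-9))
  expect_equal(round(share[length(share)], 1), 3.4)
})
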
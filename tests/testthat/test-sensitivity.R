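test_that("derivatives at the Hong Kong scenario match the published effects", {
  m <- hk_model()
  # 1-per-100,000 reduction of the healthy rate saves ~67.2 suicides/year,
  # of the high-risk rate only ~2.3 -> the ~30x Rose differential
  expect_equal(round(dz_dparam(m, "p41") * 1e-5, 1), 67.2)
  expect_equal(round(dz_dparam(m, "p42") * 1e-5, 1), 2.3)
  ratio <- dz_dparam(m, "p41") / dz_dparam(m, "p42")
  expect_gt(ratio, 29)
  expect_lt(ratio, 30)
  # the back-of-envelope shortcut (healthy count) agrees to one decimal here
  expect_equal(round(dz_dparam(m, "p41", method = "approximate") * 1e-5, 1),
               67.2)
  expect_error(dz_dparam(m, "p37"), "unknown parameter")
  expect_error(dz_dparam(m, "p21", method = "approximate"),
               "only for p41 and p42")
})

test_that("analytic derivatives agree with central finite differences", {
  set.seed(23)
  for (i in 1:200) {
    p <- random_params()
    for (nm in c("p21", "p12", "p31", "p32", "p41", "p42")) {
      a <- dz_dparam(p, nm, Q0 = 1e6)
      f <- dz_dparam(p, nm, method = "finite-difference", h = 1e-7, Q0 = 1e6)
      expect_lt(abs(a - f) / max(abs(f), 1e-8), 1e-4)
    }
  }
  # tighter agreement at the default step on the reference scenario
  m <- hk_model()
  for (nm in c("p41", "p42"))
    expect_equal(dz_dparam(m, nm),
                 dz_dparam(m, nm, method = "finite-difference", h = 1e-8),
                 tolerance = 1e-5)
})

test_that("projected reductions are linear in the perturbation", {
  m <- hk_model()
  expect_equal(project_delta_z(m, "p41", 0), 0)
  expect_equal(project_delta_z(m, "p41", 2e-5),
               2 * project_delta_z(m, "p41", 1e-5))
  expect_equal(round(project_delta_z(m, "p41", 1e-5), 1), 67.2)
})

test_that("suicide count increases in both suicide probabilities", {
  base <- coef(hk_model())
  z_at <- function(p41, p42) {
    q <- base; q[["p41"]] <- p41; q[["p42"]] <- p42
    equilibrium(validate_parameters(q), Q0 = 7e6)$counts[["z"]]
  }
  g41 <- seq(1e-5, 5e-4, length.out = 20)
  expect_true(all(diff(vapply(g41, z_at, numeric(1), p42 = 0.0025)) > 0))
  g42 <- seq(1e-4, 0.015, length.out = 20)
  expect_true(all(diff(vapply(g42, function(v) z_at(8.34e-5, v),
                              numeric(1))) > 0))
})

test_that("linearized equivalent p42 perturbation matches exact rebalancing", {
  m <- hk_model()
  lin <- equivalent_delta_p42(m, mode = "linearized")
  exa <- equivalent_delta_p42(m, mode = "exact")
  expect_lt(abs(lin - exa), 0.5e-5)
  # and across all published scenarios
  base <- coef(m)
  for (i in seq_len(nrow(published_table))) {
    q <- base
    q[["p41"]] <- published_table$p41[i]
    q[["p42"]] <- published_table$p42[i]
    q <- validate_parameters(q)
    expect_lt(abs(equivalent_delta_p42(q, mode = "linearized", Q0 = 7e6) -
                  equivalent_delta_p42(q, mode = "exact", Q0 = 7e6)),
              0.5e-5)
  }
  # linearization error vanishes with the reference perturbation
  err <- vapply(c(1e-3, 1e-4, 1e-5), function(dp)
    abs(equivalent_delta_p42(m, dp, mode = "exact") / dp -
        equivalent_delta_p42(m, dp, mode = "linearized") / dp),
    numeric(1))
  expect_true(all(diff(err) < 0))
  # unreachable targets are an error, not a silent extrapolation
  expect_error(equivalent_delta_p42(m, reference_dp41 = 0.9, mode = "exact"),
               "unreachable")
})

test_that("the scenario sweep reproduces the published table at its rounding", {
  tab <- sensitivity_table(hk_model())
  expect_equal(nrow(tab), 11)
  expect_equal(tab$p41, published_table$p41)
  expect_equal(tab$p42, published_table$p42)
  expect_equal(tab$z, published_table$z)
  expect_equal(tab$delta_z, published_table$delta_z)
  expect_equal(tab$delta_z_pct, published_table$delta_z_pct)
  expect_equal(tab$equiv_dp42_1e5, published_table$equiv_dp42_1e5)
  expect_equal(as.character(tab$block[1]), "reference")
  expect_equal(tab$ratio[tab$block == "ratio fixed"], rep(30, 3))
})

test_that("full sensitivity report is internally consistent", {
  m <- hk_model()
  s <- sensitivity(m)
  expect_equal(s$z_count, equilibrium(m)$counts[["z"]])
  expect_true(all(s$dz_dp[c("p41", "p42")] > 0))
  expect_equal(s$delta_z, 1e-5 * s$dz_dp[["p41"]])
  expect_equal(s$equivalent_dp42, s$delta_z / s$dz_dp[["p42"]])
  expect_equal(s$delta_z_over_z, s$delta_z / s$z_count)
})
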
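# Moran's I with row-normalized weights; independent oracle for the
# spatial-autocorrelation property of generated fields.
morans_i <- function(values, grid, radius = 7.1) {
  n <- length(values)
  z <- values - mean(values)
  W <- neighbor_weights(grid, neighborhood_spec(radius, 0))
  num <- as.numeric(z %*% (W %*% z))
  s0 <- sum(Matrix::rowSums(W))
  (n / s0) * num / sum(z^2)
}

test_that("generated landscapes satisfy the environmental invariants", {
  land <- generate_landscape(landscape_config(n_rows = 30, n_cols = 30, seed = 2))
  for (env in list(land$env_first, land$env_second)) {
    closure <- env$fr + env$ws + env$ag + env$bt
    expect_true(all(closure <= 1 + 1e-9))
    expect_true(all(closure >= 0))
    expect_true(all(env$scp >= 0 & env$scp <= 366))
    expect_true(all(env$msd >= 0))
    expect_true(all(env$sl >= 0))
  }
  expect_equal(nrow(land$grid), 900L)
  expect_true(all(c("hokkaido", "other") %in% land$grid$region))
  expect_error(generate_landscape(landscape_config(n_rows = 1, n_cols = 5)),
               "at least 2 x 2")
})

test_that("generated snow field is spatially autocorrelated", {
  land <- generate_landscape(landscape_config(n_rows = 30, n_cols = 30, seed = 2))
  # detrend the deliberate south-north gradient; autocorrelation must
  # remain in the residual field
  y <- land$grid$y_km
  resid <- residuals(lm(land$env_first$scp ~ y))
  expect_gt(morans_i(resid, land$grid), 0.3)
})

test_that("generators are pure functions of configuration and seed", {
  a <- generate_landscape(landscape_config(n_rows = 12, n_cols = 12, seed = 5))
  b <- generate_landscape(landscape_config(n_rows = 12, n_cols = 12, seed = 5))
  c <- generate_landscape(landscape_config(n_rows = 12, n_cols = 12, seed = 6))
  expect_identical(a$env_first$scp, b$env_first$scp)
  expect_identical(a$env_second$bt, b$env_second$bt)
  expect_false(identical(a$env_first$scp, c$env_first$scp))
})

test_that("initial occupancy follows the habitat probabilities", {
  m <- sika_habitat_model()
  land <- generate_landscape(landscape_config(n_rows = 60, n_cols = 60, seed = 3))
  # impossible habitat -> all absent
  dead <- habitat_model(m$formula, replace(coef(m), 1, -50))
  occ0 <- simulate_initial_occupancy(dead, land$env_first, land$grid, seed = 3)
  expect_equal(sum(unclass(occ0)), 0L)
  # realized prevalence concentrates around the mean occurrence probability
  occ <- simulate_initial_occupancy(m, land$env_first, land$grid, seed = 3)
  p <- plogis(as.numeric(suitability(m, land$env_first, land$grid)))
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(unclass(occ)) - mean(p)), 3 * se)
  expect_gt(mean(unclass(occ)), 0.05)
  expect_lt(mean(unclass(occ)), 0.95)
})

test_that("transitions respect stratum probabilities and edge cases", {
  ds <- make_transition_dataset(60, 60, seed = 13)
  params <- sika_dynamics_params()
  pres <- unclass(ds$occ_first) == 1L
  q_pres <- transition_probability(params, 1, ds$d[pres], ds$h[pres])
  persisted <- mean(unclass(ds$occ_second)[pres])
  se <- sqrt(sum(q_pres * (1 - q_pres))) / sum(pres)
  expect_lt(abs(persisted - mean(q_pres)), 3 * se)
  # q = 1 persistence keeps every presence
  sure <- dynamics_params(40, 0, 0, -40, 0, 0)
  occ2 <- simulate_transition(sure, ds$occ_first, ds$d, ds$h, seed = 1)
  expect_true(all(unclass(occ2)[pres] == 1L))
  # all-occupied start: no colonization stratum, still well-defined
  all_occ <- occupancy_field(rep(1L, nrow(ds$grid)), "1978")
  occ3 <- simulate_transition(sure, all_occ, ds$d, ds$h, seed = 1)
  expect_equal(sum(unclass(occ3)), nrow(ds$grid))
})

test_that("scenario bundles honor group semantics and conservation", {
  land <- generate_landscape(landscape_config(n_rows = 10, n_cols = 10, seed = 4))
  trends <- trend_config(n_members = c(baseline = 1L, lu_only = 3L,
                                       cl_only = 2L, lucl = 6L))
  sc <- generate_scenarios(land$env_second, land$grid, trends)
  expect_named(sc, c("baseline", "lu_only", "cl_only", "lucl"))
  expect_length(sc$lu_only$members, 3L)
  expect_length(sc$cl_only$members, 2L)
  expect_length(sc$lucl$members, 6L)
  # baseline: every step table equals the starting environment
  for (step in sc$baseline$members[[1]]) {
    expect_equal(step$scp, land$env_second$scp)
    expect_equal(step$ws, land$env_second$ws)
  }
  # lu_only leaves snow untouched; mass conservation of the four classes
  start_sum <- land$env_second$fr + land$env_second$ws + land$env_second$ag +
    land$env_second$bt
  for (member in sc$lu_only$members) {
    for (step in member) {
      expect_equal(step$scp, land$env_second$scp)
      expect_lt(max(abs(step$fr + step$ws + step$ag + step$bt - start_sum)),
                1e-12)
    }
  }
  # cl_only leaves land use untouched and lowers scp under a warming trend
  for (member in sc$cl_only$members) {
    final <- member[[length(member)]]
    expect_equal(final$ag, land$env_second$ag)
    expect_true(all(final$scp <= land$env_second$scp))
  }
  # default member counts mirror the 1/9/4/36 scenario families
  expect_equal(unname(trend_config()$n_members),
               c(1L, 9L, 4L, 36L))
  expect_error(trend_config(n_members = c(baseline = 1L, lu_only = 2L,
                                          cl_only = 2L, lucl = 5L)), "cross")
})

test_that("the fixture is valid, hand-checkable and fast end to end", {
  t0 <- Sys.time()
  fx <- make_fixture()
  expect_lte(nrow(fx$grid), 100L)
  closure <- fx$env_first$fr + fx$env_first$ws + fx$env_first$ag + fx$env_first$bt
  expect_true(all(closure <= 1 + 1e-9))
  # the detached strip encodes the hand-computed D cases at its first cell
  for (p in 0:2) {
    d <- suppressWarnings(
      neighborhood_occupancy(fx$occ_first, fx$grid, neighborhood_spec(10, p)))
    expect_equal(d[65], c(0.5, 2 / 3, 0.8)[p + 1])
  }
  # both strata fittable
  tab <- table(unclass(fx$occ_first), unclass(fx$occ_second))
  expect_true(all(tab >= 1))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
})

test_that("full generative pipeline recovers habitat and dynamics parameters", {
  # landscape -> occupancy histories -> refit both models; interval
  # coverage of the generating values, aggregated over parameters and
  # replicates, must be close to the nominal 95% (10 habitat coefficients
  # + 6 dynamics parameters per replicate)
  covered <- 0L; checks <- 0L
  n_rep <- 6L
  m <- sika_habitat_model()
  truth_dyn <- unclass(sika_dynamics_params())
  for (rep in seq_len(n_rep)) {
    ds <- make_transition_dataset(55, 55, seed = 900 + rep)
    hab <- fit_habitat(ds$occ_first, ds$env_first, ds$grid, m$formula)
    covered <- covered + sum(abs(coef(hab) - coef(m)) < 1.96 * hab$se)
    checks <- checks + length(coef(hab))
    fit <- fit_dynamics_mcmc(ds$data, chains = 2, iterations = 300,
                             burnin = 60, seed = rep)
    lo <- fit$summary[1:6, "2.5%"]; hi <- fit$summary[1:6, "97.5%"]
    covered <- covered + sum(truth_dyn >= lo & truth_dyn <= hi)
    checks <- checks + 6L
  }
  expect_gte(covered / checks, 0.85)
})
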
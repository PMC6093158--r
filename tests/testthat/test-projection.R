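test_that("absorbing dynamics freeze the starting occupancy", {
  fx <- make_fixture()
  frozen <- dynamics_params(30, 0, 0, -30, 0, 0) # phi -> 1, gamma -> 0
  member <- list("2028" = fx$env_second, "2053" = fx$env_second)
  cfg <- projection_config(replicates = 50, threshold = 0.1725, seed = 8,
                           dispersal = neighborhood_spec(25, 2),
                           params = frozen)
  res <- suppressWarnings(project_scenario(sika_habitat_model(), fx$occ_second,
                                           fx$grid, member, cfg))
  x0 <- as.numeric(unclass(fx$occ_second))
  expect_equal(unname(res$freq[, 1]), x0)
  expect_equal(unname(res$freq[, 2]), x0)
})

test_that("single-cell dynamics match the two-state Markov chain marginal", {
  g <- cell_grid(1L, 0, 0, "other")
  e <- env_table("s", 1L, scp = 0, msd = 0, fr = 0, ws = 0, ag = 0, bt = 0,
                 sl = 0)
  member <- list("1" = e, "2" = e, "3" = e, "4" = e)
  # intercept-only rates; D = 0 (isolated), H contributes 0 via zero env
  gam <- 0.2076; phi <- 0.55
  params <- dynamics_params(qlogis(phi), 0, 0, qlogis(gam), 0, 0)
  model <- habitat_model(habitat_formula(FALSE, "none", FALSE),
                         c(intercept = 0))
  cfg <- projection_config(replicates = 1000, threshold = 0.5, seed = 4,
                           dispersal = neighborhood_spec(10, 0),
                           params = params)
  res <- suppressWarnings(project_scenario(model, occupancy_field(0L, "0"),
                                           g, member, cfg))
  p <- 0
  for (k in 1:4) {
    p <- p * phi + (1 - p) * gam # closed-form chain marginal
    mc_tol <- 3 * sqrt(p * (1 - p) / 1000)
    expect_lt(abs(res$freq[1, k] - p), mc_tol)
  }
})

test_that("potential area counts strictly-exceeding cells", {
  freq <- seq(0, 0.9, by = 0.1)
  areas <- rep(23.06, 10)
  expect_equal(potential_area(freq, 0.1725, areas), 8 * 23.06)
  expect_equal(potential_area(rep(0.05, 10), 0.1725, areas), 0)
  expect_equal(potential_area(freq, 0, areas), 9 * 23.06) # zero stays out
  expect_error(potential_area(c(0.5, 1.2), 0.5, c(1, 1)), "0, 1")
})

test_that("percent change reproduces the published scenario bounds", {
  expect_equal(percent_change(308.5e3, 304.2e3), 1.4)
  expect_equal(percent_change(312.1e3, 304.2e3), 2.6)
  expect_equal(percent_change(313.7e3, 304.2e3), 3.1)
  expect_equal(percent_change(334.0e3, 304.2e3), 9.8)
  expect_equal(percent_change(318.3e3, 304.2e3), 4.6)
  expect_equal(percent_change(340.4e3, 304.2e3), 11.9)
  expect_equal(percent_change(100, 100), 0.0)
  expect_error(percent_change(100, 0), "positive")
})

test_that("group aggregation averages members and bounds them at 95%", {
  fake_result <- function(a1, a2) {
    structure(list(freq = cbind("1" = c(a1 / 200, 0.5), "2" = c(a2 / 200, 0.5)),
                   area_km2 = c("1" = a1, "2" = a2), steps = c("1", "2"),
                   replicates = 100, threshold = 0.5),
              class = "projection_result")
  }
  single <- aggregate_group(list(m = fake_result(100, 150)))
  expect_equal(single$area_series$mean, c(100, 150))
  expect_equal(unname(single$mean_freq), unname(fake_result(100, 150)$freq))
  two <- aggregate_group(list(a = fake_result(100, 100), b = fake_result(300, 200)))
  expect_equal(two$area_series$mean, c(200, 150))
  members <- lapply(seq(100, 400, length.out = 12),
                    function(a) fake_result(a, a / 2))
  agg <- aggregate_group(members)
  # the 95% band stays inside the member range and, for this few members,
  # leaves out at most the two extremes
  a1 <- agg$member_areas[, 1]
  expect_gte(agg$area_series$lo95[1], min(a1))
  expect_lte(agg$area_series$hi95[1], max(a1))
  inside <- sum(a1 >= agg$area_series$lo95[1] & a1 <= agg$area_series$hi95[1])
  expect_gte(inside, length(a1) - 2L)
})

test_that("projections are reproducible and frequencies are multiples of 1/R", {
  fx <- make_fixture()
  member <- list("2028" = fx$env_second, "2053" = fx$env_second)
  cfg <- projection_config(replicates = 40, threshold = 0.1725, seed = 12,
                           dispersal = neighborhood_spec(25, 2),
                           params = sika_dynamics_params())
  r1 <- suppressWarnings(project_scenario(sika_habitat_model(), fx$occ_second,
                                          fx$grid, member, cfg))
  r2 <- suppressWarnings(project_scenario(sika_habitat_model(), fx$occ_second,
                                          fx$grid, member, cfg))
  expect_identical(r1$freq, r2$freq)
  expect_true(all(abs(r1$freq * 40 - round(r1$freq * 40)) < 1e-9))
  # error on a member that is not keyed by step year
  expect_error(project_scenario(sika_habitat_model(), fx$occ_second, fx$grid,
                                list(fx$env_second), cfg), "named list")
})

test_that("a snow-cover decline expands the projected range", {
  # scp enters negatively, so lowering it raises suitability and the
  # projected area should not fall below the constant-environment run
  ds <- make_transition_dataset(20, 20, seed = 71)
  env0 <- ds$env_second
  env_warm <- env_table("w", env0$cell_id, pmax(0, env0$scp - 25), env0$msd,
                        env0$fr, env0$ws, env0$ag, env0$bt, env0$sl)
  base_member <- list("2028" = env0, "2053" = env0)
  warm_member <- list("2028" = env_warm, "2053" = env_warm)
  cfg <- projection_config(replicates = 150, threshold = 0.1725, seed = 5,
                           dispersal = neighborhood_spec(25, 2),
                           params = sika_dynamics_params())
  m <- sika_habitat_model()
  base <- suppressWarnings(project_scenario(m, ds$occ_second, ds$grid,
                                            base_member, cfg))
  warm <- suppressWarnings(project_scenario(m, ds$occ_second, ds$grid,
                                            warm_member, cfg))
  expect_gte(warm$area_km2[[2]], base$area_km2[[2]])
})
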
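test_that("transition probability evaluates the stratum logistic forms", {
  p0 <- dynamics_params(0, 0, 0, 0, 0, 0)
  expect_equal(transition_probability(p0, c(0, 1), c(0.3, 0.9), c(-2, 5)),
               c(0.5, 0.5))
  p <- sika_dynamics_params()
  expect_equal(transition_probability(p, 0, 0, 0), plogis(-1.34),
               tolerance = 1e-12)
  expect_equal(transition_probability(p, 0, 0, 0), 0.2076, tolerance = 1e-3)
  expect_equal(transition_probability(p, 1, 1, 0), 0.9973, tolerance = 1e-4)
  # strictly increasing in d and h when slopes positive
  d_grid <- seq(0, 1, by = 0.1)
  for (xp in 0:1) {
    q_d <- transition_probability(p, xp, d_grid, 0)
    expect_true(all(diff(q_d) > 0))
    q_h <- transition_probability(p, xp, 0.5, seq(-3, 3, by = 0.5))
    expect_true(all(diff(q_h) > 0))
  }
})

test_that("transition log-likelihood matches closed forms", {
  p0 <- dynamics_params(0, 0, 0, 0, 0, 0)
  td4 <- transition_data(c(0, 1, 0, 1), c(1, 0, 0, 1), rep(0.5, 4), rep(0, 4))
  expect_equal(dynamics_loglik(p0, td4)$total, 4 * log(0.5), tolerance = 1e-12)
  # q = 0.8 persistence / q = 0.3 colonization hand case
  p <- dynamics_params(qlogis(0.8), 0, 0, qlogis(0.3), 0, 0)
  td2 <- transition_data(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  expect_equal(dynamics_loglik(p, td2)$total, log(0.8) + log(0.7),
               tolerance = 1e-12)
  # perfect prediction contributes ~0 (clipped, never -Inf)
  p_sure <- dynamics_params(40, 0, 0, -40, 0, 0)
  td_ok <- transition_data(c(1, 0), c(1, 0), c(0, 0), c(0, 0))
  expect_equal(dynamics_loglik(p_sure, td_ok)$per_cell, c(0, 0),
               tolerance = 1e-9)
  p_wrong <- dynamics_params(-40, 0, 0, 40, 0, 0)
  expect_true(is.finite(dynamics_loglik(p_wrong, td_ok)$total))
})

test_that("WAIC matches the degenerate closed form and is penalized correctly", {
  # point-mass posterior at q = 0.5, n = 2
  ll <- matrix(log(0.5), nrow = 5, ncol = 2)
  w <- waic(ll)
  expect_equal(w$waic_per_obs, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(w$p_waic, 0)
  expect_error(waic(matrix(log(0.5), 1, 2)), "two posterior draws")
  set.seed(42)
  for (k in 1:5) {
    llr <- matrix(rnorm(200, mean = -1), 20, 10)
    expect_gte(waic(llr)$p_waic, 0)
  }
})

test_that("WAIC prefers the generating model in most replicates", {
  # Data from the full transition model; the competitor sees permuted
  # covariates (association destroyed), so the generating model should
  # win on WAIC nearly always.
  wins <- 0L
  for (rep in 1:20) {
    ds <- make_transition_dataset(45, 45, seed = 300 + rep)
    fit_true <- fit_dynamics_mcmc(ds$data, chains = 2, iterations = 200,
                                  burnin = 50, seed = rep)
    set.seed(rep)
    perm <- sample.int(nrow(ds$data))
    data_perm <- transition_data(ds$data$x_first, ds$data$x_second,
                                 ds$data$d[perm], ds$data$h[perm])
    fit_perm <- fit_dynamics_mcmc(data_perm, chains = 2, iterations = 200,
                                  burnin = 50, seed = rep)
    if (fit_true$waic$waic_per_obs < fit_perm$waic$waic_per_obs) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("rhat flags separated chains and passes identical ones", {
  set.seed(1)
  base <- rnorm(1000)
  expect_lte(rhat(cbind(base, base, base)), 1 + 1e-9)
  expect_gt(rhat(cbind(rnorm(1000), rnorm(1000, 10))), 3)
  expect_warning(r <- rhat(matrix(1, 100, 2)), "zero within-chain")
  expect_equal(r, 1.0)
  expect_error(rhat(matrix(0, 5, 2)), "at least")
})

test_that("rank-based AUC handles separation, ties and the 4-pair case", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 3 / 4)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  # independent cross-check against pROC on a random problem
  set.seed(7)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  reference <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<")))
  expect_equal(auc(scores, labels), reference, tolerance = 1e-12)
})

test_that("sensitivity threshold keeps the target fraction of presences", {
  expect_equal(sensitivity_threshold(seq(0.05, 1, by = 0.05), 0.95), 0.10)
  expect_equal(sensitivity_threshold(c(0.2, 0.4, 0.6, 0.8, 1.0), 0.95), 0.2)
  expect_equal(sensitivity_threshold(c(0.3, 0.9, 0.1), 1.0), 0.1)
  expect_error(sensitivity_threshold(numeric(0)), "non-empty")
  # exhaustive check over order statistics on random score sets
  set.seed(5)
  for (k in 1:10) {
    s <- round(runif(40), 2)
    t_star <- sensitivity_threshold(s, 0.9)
    expect_gte(mean(s >= t_star), 0.9)
    larger <- sort(unique(s))[sort(unique(s)) > t_star]
    for (u in larger) expect_lt(mean(s >= u), 0.9)
  }
})

test_that("MCMC recovers generating parameters and factorizes over strata", {
  ds <- make_transition_dataset(60, 60, seed = 21)
  fit <- fit_dynamics_mcmc(ds$data, chains = 3, iterations = 600, burnin = 100,
                           seed = 21)
  expect_true(fit$converged)
  expect_true(all(fit$summary[1:6, "rhat"] < 1.1))
  truth <- unclass(sika_dynamics_params())
  med <- fit$summary[1:6, "50%"]
  sdv <- fit$summary[1:6, "sd"]
  expect_true(all(abs(med - truth) < 3 * sdv))
  # quantiles monotone
  qs <- as.matrix(fit$summary[1:6, c("2.5%", "25%", "50%", "75%", "97.5%")])
  expect_true(all(apply(qs, 1, function(v) all(diff(v) >= 0))))
  # posterior medians agree with the factorized MLE (independent stats::glm
  # fits per stratum) within 2 Monte-Carlo standard errors + MLE SE
  df <- as.data.frame(ds$data)
  mle_phi <- glm(x_second ~ d + h, binomial, df[df$x_first == 1, ])
  mle_gam <- glm(x_second ~ d + h, binomial, df[df$x_first == 0, ])
  mle <- c(coef(mle_phi), coef(mle_gam))
  for (j in 1:6) {
    mcse <- mcse_batch(fit$draws[, j])
    tol <- 2 * mcse + 0.1 * fit$summary[j, "sd"]
    expect_lt(abs(fit$summary[j, "50%"] - mle[j]), tol + 0.05)
  }
})

test_that("degenerate strata are rejected before sampling", {
  td <- transition_data(rep(1, 20), rbinom(20, 1, 0.5), runif(20), rnorm(20))
  expect_error(fit_dynamics_mcmc(td), "stratum")
  td2 <- transition_data(rep(c(0, 1), 10), rep(1, 20), runif(20), rnorm(20))
  expect_error(fit_dynamics_mcmc(td2), "both outcomes")
})

test_that("posterior export files carry draws and summary", {
  ds <- make_transition_dataset(20, 20, seed = 33)
  fit <- fit_dynamics_mcmc(ds$data, chains = 2, iterations = 100, burnin = 20,
                           seed = 33)
  td <- withr::local_tempdir()
  write_dynamics_draws(fit, file.path(td, "draws.csv"))
  draws <- read.csv(file.path(td, "draws.csv"))
  expect_equal(nrow(draws), 200L)
  expect_named(draws, c("chain", "iter", "phi0", "phi_d", "phi_h",
                        "gam0", "gam_d", "gam_h", "loglik"))
  write_dynamics_summary(fit, file.path(td, "summary.json"))
  js <- jsonlite::read_json(file.path(td, "summary.json"))
  expect_length(js$summary, 7L)
})
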
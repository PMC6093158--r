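#' Persistence-colonization parameter set
#'
#' The six parameters of the transition model on the logit scale:
#' persistence intercept/slopes (`phi0`, `phi_d`, `phi_h`) applied to cells
#' occupied at the first survey, and colonization intercept/slopes
#' (`gam0`, `gam_d`, `gam_h`) applied to cells unoccupied then.  Slopes
#' `*_d` act on the dispersal covariate D, `*_h` on habitat suitability H.
#'
#' @param phi0,phi_d,phi_h,gam0,gam_d,gam_h finite reals.
#' @return Named numeric vector of class `dynamics_params`.
#' @export
dynamics_params <- function(phi0, phi_d, phi_h, gam0, gam_d, gam_h) {
  p <- c(phi0 = unname(phi0), phi_d = unname(phi_d), phi_h = unname(phi_h),
         gam0 = unname(gam0), gam_d = unname(gam_d), gam_h = unname(gam_h))
  if (!all(is.finite(p))) stop("dynamics parameters must be finite", call. = FALSE)
  structure(p, class = "dynamics_params")
}

.param_names <- c("phi0", "phi_d", "phi_h", "gam0", "gam_d", "gam_h")

#' @export
print.dynamics_params <- function(x, ...) {
  cat("dynamics_params (logit scale):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Per-cell transition data
#'
#' Aligns the four per-cell inputs of the transition model: occupancy at
#' the two surveys, the dispersal covariate D (in [0, 1]) and habitat
#' suitability H (log odds).
#'
#' @param x_first,x_second binary 0/1 occupancy at the two surveys.
#' @param d dispersal covariate in [0, 1].
#' @param h habitat suitability (log odds).
#' @return A `data.frame` of class `transition_data` with columns
#'   `x_first`, `x_second`, `d`, `h`.
#' @export
transition_data <- function(x_first, x_second, d, h) {
  n <- length(x_first)
  stop_if_not_aligned(length(x_second), n, "x_second", "x_first")
  stop_if_not_aligned(length(d), n, "d", "x_first")
  stop_if_not_aligned(length(h), n, "h", "x_first")
  x_first <- as.integer(x_first); x_second <- as.integer(x_second)
  if (!all(x_first %in% 0:1) || !all(x_second %in% 0:1)) {
    stop("occupancy values must be 0 or 1", call. = FALSE)
  }
  d <- as.numeric(d); h <- as.numeric(h)
  if (any(d < -1e-9 | d > 1 + 1e-9)) stop("d must lie in [0, 1]", call. = FALSE)
  if (!all(is.finite(h))) stop("h must be finite", call. = FALSE)
  structure(data.frame(x_first = x_first, x_second = x_second, d = d, h = h),
            class = c("transition_data", "data.frame"))
}

#' Transition probability of the dynamic occupancy model
#'
#' Probability that a cell is occupied at the second survey given its state
#' at the first: logistic(phi0 + phi_d D + phi_h H) for previously occupied
#' cells (persistence) and logistic(gam0 + gam_d D + gam_h H) for
#' previously empty cells (colonization).  Vectorized over cells.
#'
#' @param params a [dynamics_params()].
#' @param x_prev binary previous occupancy (0/1), vectorized.
#' @param d dispersal covariate.
#' @param h habitat suitability (log odds).
#' @return Probabilities in (0, 1).
#' @examples
#' p <- dynamics_params(-0.04, 5.94, 0.50, -1.34, 8.28, 0.64)
#' transition_probability(p, 0, 0, 0)  # colonization at D = H = 0
#' @export
transition_probability <- function(params, x_prev, d, h) {
  stopifnot(inherits(params, "dynamics_params"))
  n <- max(length(x_prev), length(d), length(h))
  x_prev <- rep_len(as.numeric(x_prev), n)
  d <- rep_len(as.numeric(d), n); h <- rep_len(as.numeric(h), n)
  eta <- ifelse(x_prev == 1,
                params[["phi0"]] + params[["phi_d"]] * d + params[["phi_h"]] * h,
                params[["gam0"]] + params[["gam_d"]] * d + params[["gam_h"]] * h)
  clip_prob(stats::plogis(eta))
}

#' Bernoulli log-likelihood of the transition model
#'
#' @param params a [dynamics_params()].
#' @param data a [transition_data()].
#' @return List with `total` and `per_cell` log-likelihood contributions.
#' @export
dynamics_loglik <- function(params, data) {
  stopifnot(inherits(data, "transition_data"))
  q <- transition_probability(params, data$x_first, data$d, data$h)
  ll <- ifelse(data$x_second == 1L, log(q), log1p(-q))
  list(total = sum(ll), per_cell = ll)
}

# Stratum-wise logistic MLE of the transition model; the likelihood
# factorizes over the two first-survey strata, so the joint MLE is two
# independent logistic fits.  Used to initialize and shape MCMC proposals.
.dynamics_mle <- function(data) {
  fit_stratum <- function(sub) {
    f <- stats::glm(x_second ~ d + h, family = stats::binomial(),
                    data = as.data.frame(sub))
    list(coef = unname(stats::coef(f)), vcov = unname(stats::vcov(f)))
  }
  list(phi = fit_stratum(data[data$x_first == 1L, ]),
       gam = fit_stratum(data[data$x_first == 0L, ]))
}

# Random-walk Metropolis on one 3-parameter stratum block under a flat
# prior.  Proposal is multivariate normal with covariance 2.4^2/3 times
# the MLE covariance (Laplace-calibrated).  Returns draws and per-draw
# stratum log-likelihoods.
.sample_block <- function(y, X, init, prop_chol, n_iter, burnin) {
  loglik <- function(theta) {
    q <- clip_prob(stats::plogis(as.numeric(X %*% theta)))
    sum(ifelse(y == 1L, log(q), log1p(-q)))
  }
  theta <- init
  ll <- loglik(theta)
  keep <- matrix(NA_real_, n_iter, 3L)
  keep_ll <- numeric(n_iter)
  acc <- 0L
  total <- burnin + n_iter
  for (it in seq_len(total)) {
    prop <- theta + as.numeric(prop_chol %*% stats::rnorm(3L))
    ll_prop <- loglik(prop)
    if (log(stats::runif(1L)) < ll_prop - ll) {
      theta <- prop; ll <- ll_prop; acc <- acc + 1L
    }
    if (it > burnin) {
      keep[it - burnin, ] <- theta
      keep_ll[it - burnin] <- ll
    }
  }
  list(draws = keep, loglik = keep_ll, accept = acc / total)
}

#' Fit the persistence-colonization model by MCMC
#'
#' Posterior sampling of the six transition parameters under flat
#' (noninformative) priors.  Because the likelihood factorizes over the
#' two first-survey strata, the sampler updates the persistence and
#' colonization blocks independently with random-walk Metropolis proposals
#' calibrated from the stratum-wise logistic MLE.  Defaults are three
#' chains of 1,000 retained iterations after a 100-iteration burn-in.
#'
#' Pointwise per-draw log-likelihoods are accumulated in streaming form so
#' WAIC is available at any problem size without storing a draws-by-cells
#' matrix.
#'
#' @param data a [transition_data()]; both strata must contain both
#'   outcomes.
#' @param chains number of chains.
#' @param iterations retained iterations per chain.
#' @param burnin discarded initial iterations per chain.
#' @param seed integer seed (chains get independent derived streams).
#' @param pointwise if `TRUE` also return the draws x cells log-likelihood
#'   matrix (memory permitting; intended for small n).
#' @return A list of class `dynamics_fit`: `draws` (draws x 6 matrix),
#'   `chain` (chain index per draw), `summary` (mean, sd, quantiles, Rhat
#'   per parameter plus a deviance row), `waic` (list from the pointwise
#'   accumulation), `deviance` (per-draw deviances), `accept`, `converged`
#'   (all Rhat <= 1.1), `n`.
#' @export
fit_dynamics_mcmc <- function(data, chains = 3L, iterations = 1000L,
                              burnin = 100L, seed = 1L, pointwise = FALSE) {
  stopifnot(inherits(data, "transition_data"))
  for (s in c(0L, 1L)) {
    ys <- data$x_second[data$x_first == s]
    if (length(ys) == 0L || length(unique(ys)) < 2L) {
      stop(sprintf("stratum x_first = %d must be non-empty with both outcomes represented", s),
           call. = FALSE)
    }
  }
  mle <- .dynamics_mle(data)
  scale2 <- (2.4^2) / 3
  chol_phi <- t(chol(scale2 * mle$phi$vcov))
  chol_gam <- t(chol(scale2 * mle$gam$vcov))
  i1 <- data$x_first == 1L
  X1 <- cbind(1, data$d[i1], data$h[i1]); y1 <- data$x_second[i1]
  X0 <- cbind(1, data$d[!i1], data$h[!i1]); y0 <- data$x_second[!i1]

  draws <- matrix(NA_real_, chains * iterations, 6L,
                  dimnames = list(NULL, .param_names))
  chain_id <- rep(seq_len(chains), each = iterations)
  loglik_draw <- numeric(chains * iterations)
  accept <- matrix(NA_real_, chains, 2L, dimnames = list(NULL, c("phi", "gam")))
  for (cc in seq_len(chains)) {
    set.seed(derive_seed(seed, paste0("dynamics-chain-", cc)))
    init_phi <- mle$phi$coef + as.numeric(chol_phi %*% stats::rnorm(3L))
    init_gam <- mle$gam$coef + as.numeric(chol_gam %*% stats::rnorm(3L))
    bp <- .sample_block(y1, X1, init_phi, chol_phi, iterations, burnin)
    bg <- .sample_block(y0, X0, init_gam, chol_gam, iterations, burnin)
    rows <- which(chain_id == cc)
    draws[rows, 1:3] <- bp$draws
    draws[rows, 4:6] <- bg$draws
    loglik_draw[rows] <- bp$loglik + bg$loglik
    accept[cc, ] <- c(bp$accept, bg$accept)
  }

  # Streaming pointwise WAIC accumulation (chunked over draws).
  n <- nrow(data)
  M <- nrow(draws)
  s_lik <- numeric(n); s_ll <- numeric(n); s_ll2 <- numeric(n)
  want_pw <- isTRUE(pointwise)
  pw <- if (want_pw) matrix(NA_real_, M, n) else NULL
  chunk <- max(1L, min(M, floor(2e6 / n)))
  idx1 <- which(i1); idx0 <- which(!i1)
  for (start in seq(1L, M, by = chunk)) {
    rows <- start:min(M, start + chunk - 1L)
    th <- draws[rows, , drop = FALSE]
    ll_chunk <- matrix(NA_real_, length(rows), n)
    eta1 <- X1 %*% t(th[, 1:3, drop = FALSE])
    q1 <- clip_prob(stats::plogis(eta1))
    ll1 <- log(ifelse(rep(y1, length(rows)) == 1L, q1, 1 - q1))
    dim(ll1) <- dim(q1)
    ll_chunk[, idx1] <- t(ll1)
    eta0 <- X0 %*% t(th[, 4:6, drop = FALSE])
    q0 <- clip_prob(stats::plogis(eta0))
    ll0 <- log(ifelse(rep(y0, length(rows)) == 1L, q0, 1 - q0))
    dim(ll0) <- dim(q0)
    ll_chunk[, idx0] <- t(ll0)
    s_lik <- s_lik + colSums(exp(ll_chunk))
    s_ll <- s_ll + colSums(ll_chunk)
    s_ll2 <- s_ll2 + colSums(ll_chunk^2)
    if (want_pw) pw[rows, ] <- ll_chunk
  }
  lppd_i <- log(s_lik / M)
  p_i <- (s_ll2 - s_ll^2 / M) / (M - 1)
  waic <- list(waic_per_obs = -2 * sum(lppd_i - p_i) / n,
               lppd = sum(lppd_i), p_waic = sum(p_i), n = n)

  per_chain <- lapply(seq_len(chains), function(cc) draws[chain_id == cc, , drop = FALSE])
  rhats <- vapply(.param_names, function(p) {
    rhat(vapply(per_chain, function(m) m[, p], numeric(iterations)))
  }, numeric(1))
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summ <- data.frame(
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    t(apply(draws, 2, stats::quantile, probs = qs)),
    rhat = rhats, check.names = FALSE)
  colnames(summ)[3:7] <- c("2.5%", "25%", "50%", "75%", "97.5%")
  deviance <- -2 * loglik_draw
  dev_chains <- vapply(seq_len(chains),
                       function(cc) deviance[chain_id == cc], numeric(iterations))
  summ <- rbind(summ, deviance = c(mean(deviance), stats::sd(deviance),
                                   stats::quantile(deviance, qs),
                                   rhat(dev_chains)))
  converged <- all(rhats <= 1.1)
  if (!converged) {
    warning("some Rhat values exceed 1.1; chains may not have converged", call. = FALSE)
  }
  structure(list(draws = draws, chain = chain_id, summary = summ,
                 waic = waic, deviance = deviance, accept = accept,
                 pointwise_loglik = pw, converged = converged, n = n,
                 chains = chains, iterations = iterations, burnin = burnin),
            class = "dynamics_fit")
}

#' @export
coef.dynamics_fit <- function(object, ...) {
  med <- apply(object$draws, 2, stats::median)
  dynamics_params(med[1], med[2], med[3], med[4], med[5], med[6])
}

#' @export
print.dynamics_fit <- function(x, ...) {
  cat(sprintf("dynamics_fit: %d cells, %d chains x %d iterations (burn-in %d)\n",
              x$n, x$chains, x$iterations, x$burnin))
  cat(sprintf("WAIC per observation = %.4f; converged: %s\n",
              x$waic$waic_per_obs, x$converged))
  print(round(x$summary, 2))
  invisible(x)
}

#' @export
summary.dynamics_fit <- function(object, ...) object$summary

#' @export
plot.dynamics_fit <- function(x, pars = .param_names, ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::matplot(matrix(x$draws[, p], ncol = x$chains), type = "l",
                      lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Watanabe-Akaike information criterion, per observation
#'
#' WAIC from a draws-by-observations matrix of pointwise log-likelihoods:
#' lppd_i = log mean over draws of the likelihood, p_i = variance over
#' draws of the log-likelihood (the variance-based effective-parameter
#' form), and waic_per_obs = -2 sum(lppd_i - p_i) / n.  Reported per
#' observation so values are comparable across data sizes.
#'
#' @param loglik matrix with one row per posterior draw and one column per
#'   observation.
#' @return List with `waic_per_obs`, `lppd`, `p_waic`, `n`.
#' @export
waic <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (nrow(loglik) < 2L) {
    stop("WAIC needs at least two posterior draws (variance undefined otherwise)",
         call. = FALSE)
  }
  m <- apply(loglik, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(loglik, 2, m)))) # stable log-mean-exp
  p_i <- apply(loglik, 2, stats::var)
  n <- ncol(loglik)
  list(waic_per_obs = -2 * sum(lppd_i - p_i) / n,
       lppd = sum(lppd_i), p_waic = sum(p_i), n = n)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Rhat = sqrt(((n-1)/n W + B/n) / W) with W the mean within-chain variance
#' and B the between-chain variance of the chain means (times n).
#'
#' @param chains matrix with one column per chain (iterations in rows), or
#'   a list of equal-length numeric vectors.
#' @return Rhat (scalar).
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L || n < 10L) {
    stop("rhat needs at least 2 chains of at least 10 draws", call. = FALSE)
  }
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) {
    warning("zero within-chain variance; Rhat reported as 1", call. = FALSE)
    return(1.0)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney AUC: the probability that a random positive scores higher
#' than a random negative, with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 observed labels (both classes present).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  stop_if_not_aligned(length(scores), length(labels), "scores", "labels")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores) # mean ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Sensitivity-based presence threshold
#'
#' The largest score cutoff that still classifies at least a target
#' fraction (default 95%) of observed presences as present, prioritizing
#' the avoidance of false negatives at range boundaries.
#'
#' @param presence_scores predicted occurrence probabilities at cells with
#'   observed presence.
#' @param target_sensitivity required fraction of presences retained, in
#'   (0, 1].
#' @return The threshold (one of the observed scores).
#' @export
sensitivity_threshold <- function(presence_scores, target_sensitivity = 0.95) {
  n <- length(presence_scores)
  if (n < 1L) stop("presence scores must be non-empty", call. = FALSE)
  if (target_sensitivity <= 0 || target_sensitivity > 1) {
    stop("target_sensitivity must lie in (0, 1]", call. = FALSE)
  }
  s <- sort(presence_scores)
  u <- unique(s)
  n_ge <- n - match(u, s) + 1L # scores >= u, via first occurrence in sorted order
  max(u[n_ge / n >= target_sensitivity])
}

#' Export posterior draws / summary of a dynamics fit
#'
#' @param fit a [fit_dynamics_mcmc()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @name dynamics_io
NULL

#' @rdname dynamics_io
#' @export
write_dynamics_draws <- function(fit, path) {
  stopifnot(inherits(fit, "dynamics_fit"))
  df <- data.frame(chain = fit$chain,
                   iter = stats::ave(fit$chain, fit$chain, FUN = seq_along),
                   fit$draws, loglik = -fit$deviance / 2, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dynamics_io
#' @export
write_dynamics_summary <- function(fit, path) {
  stopifnot(inherits(fit, "dynamics_fit"))
  obj <- list(summary = cbind(parameter = rownames(fit$summary),
                              as.data.frame(fit$summary)),
              waic = fit$waic, converged = fit$converged, n = fit$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
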
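#' Candidate specification for the model-selection sweep
#'
#' One candidate = a habitat formula (one of the 84), the epoch whose
#' environmental table provides the suitability surface, and a dispersal
#' neighborhood (one of the 15 radius x weight combinations).  The full
#' grid has 84 x 2 x 15 = 2,520 candidates.
#'
#' @param formula a [habitat_formula()].
#' @param epoch epoch label whose environment supplies the surface.
#' @param dispersal a [neighborhood_spec()] for the dispersal covariate D.
#' @return A list of class `candidate_spec`.
#' @export
candidate_spec <- function(formula, epoch, dispersal) {
  stopifnot(inherits(formula, "habitat_formula"),
            inherits(dispersal, "neighborhood_spec"))
  structure(list(formula = formula, epoch = as.character(epoch),
                 dispersal = dispersal),
            class = "candidate_spec")
}

#' @export
format.candidate_spec <- function(x, ...) {
  sprintf("%s | surface %s | D(%s)", format(x$formula), x$epoch,
          format(x$dispersal))
}

#' @export
print.candidate_spec <- function(x, ...) {
  cat("candidate_spec:", format(x), "\n")
  invisible(x)
}

#' Enumerate the candidate grid
#'
#' Crosses the habitat formulae with surface epochs and dispersal
#' neighborhoods.  Defaults reproduce the full sweep: 84 formulae (with
#' autocovariate options) x 2 epochs x 15 dispersal specs = 2,520.
#'
#' @param formulas list of [habitat_formula()] (default
#'   `enumerate_habitat_formulas(TRUE)`).
#' @param epochs character epoch labels.
#' @param radii_km dispersal radii in km.
#' @param weight_exponents dispersal weight exponents.
#' @return List of [candidate_spec()].
#' @export
build_candidate_grid <- function(formulas = enumerate_habitat_formulas(TRUE),
                                 epochs = c("1978", "2003"),
                                 radii_km = c(10, 25, 50, 75, 100),
                                 weight_exponents = c(0, 1, 2)) {
  disp <- list()
  for (r in radii_km) for (p in weight_exponents) {
    disp <- c(disp, list(neighborhood_spec(r, p)))
  }
  out <- vector("list", length(formulas) * length(epochs) * length(disp))
  k <- 0L
  for (f in formulas) for (ep in epochs) for (dd in disp) {
    k <- k + 1L
    out[[k]] <- candidate_spec(f, ep, dd)
  }
  out
}

# Ranking order: WAIC ascending (failed fits last), ties broken by fewer
# habitat terms, then smaller dispersal radius.
.rank_candidate_order <- function(waic, n_terms, radius) {
  order(is.na(waic), waic, n_terms, radius)
}

#' Fit and rank candidate models by WAIC
#'
#' For each candidate: the habitat model is fitted once per formula on the
#' first-survey data and reused, the suitability surface is evaluated on
#' the candidate's epoch, the dispersal covariate is computed once per
#' neighborhood spec from the first-survey occupancy, and the transition
#' model is fitted by MCMC.  Candidates are ranked by per-observation WAIC
#' (ascending); ties are broken by fewer habitat terms, then smaller
#' dispersal radius.  AUC is the rank-based AUC of the fitted transition
#' probabilities against second-survey occupancy.
#'
#' @param candidates list of [candidate_spec()].
#' @param occ_first,occ_second [occupancy_field()]s of the two surveys.
#' @param env_list named list of [env_table()]s keyed by epoch label; the
#'   entry named `train_epoch` trains the habitat models.
#' @param grid the [cell_grid()].
#' @param train_epoch epoch label used to train habitat models (default the
#'   first entry of `env_list`).
#' @param chains,iterations,burnin MCMC settings per candidate.
#' @param seed master seed; each candidate gets a derived stream.
#' @return A `data.frame` of class `ranking_table` sorted by WAIC with
#'   columns `rank`, `radius_km`, `weight`, `formula`, `epoch`, `waic`,
#'   `auc`; fitted artifacts are kept in attributes `fits` and `candidates`
#'   (ordered as the rows).
#' @export
evaluate_candidates <- function(candidates, occ_first, occ_second, env_list,
                                grid, train_epoch = names(env_list)[1],
                                chains = 3L, iterations = 1000L, burnin = 100L,
                                seed = 1L) {
  stopifnot(length(candidates) > 0, is.list(env_list), !is.null(names(env_list)))
  env_train <- env_list[[train_epoch]]
  if (is.null(env_train)) stop("train_epoch not found in env_list", call. = FALSE)

  habitat_cache <- new.env(parent = emptyenv())
  d_cache <- new.env(parent = emptyenv())
  get_d <- function(spec) {
    key <- sprintf("%g:%g", spec$radius_km, spec$weight_exponent)
    if (is.null(d_cache[[key]])) {
      d_cache[[key]] <- suppressWarnings(
        neighborhood_occupancy(occ_first, grid, spec))
    }
    d_cache[[key]]
  }
  get_habitat <- function(formula) {
    key <- format(formula)
    if (is.null(habitat_cache[[key]])) {
      ac_d <- if (!is.null(formula$autocov)) get_d(formula$autocov)
      habitat_cache[[key]] <- fit_habitat(occ_first, env_train, grid, formula,
                                          autocov_d = ac_d)
    }
    habitat_cache[[key]]
  }

  k <- length(candidates)
  waic_v <- rep(NA_real_, k); auc_v <- rep(NA_real_, k)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    sp <- candidates[[i]]
    res <- tryCatch({
      hm <- get_habitat(sp$formula)
      env_s <- env_list[[sp$epoch]]
      if (is.null(env_s)) stop(sprintf("epoch '%s' not found in env_list", sp$epoch))
      ac_d <- if (!is.null(sp$formula$autocov)) get_d(sp$formula$autocov)
      h <- suitability(hm, env_s, grid, autocov_d = ac_d)
      d <- get_d(sp$dispersal)
      td <- transition_data(unclass(occ_first), unclass(occ_second),
                            d, as.numeric(h))
      fit <- fit_dynamics_mcmc(td, chains = chains, iterations = iterations,
                               burnin = burnin,
                               seed = derive_seed(seed, paste0("candidate-", i)))
      q <- transition_probability(coef(fit), td$x_first, td$d, td$h)
      list(habitat = hm, dynamics = fit,
           waic = fit$waic$waic_per_obs,
           auc = auc(q, td$x_second))
    }, error = function(e) {
      warning(sprintf("candidate %d (%s) failed: %s", i, format(sp),
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      waic_v[i] <- res$waic
      auc_v[i] <- res$auc
      fits[[i]] <- res[c("habitat", "dynamics")]
    }
  }
  n_terms <- vapply(candidates, function(sp) .n_habitat_terms(sp$formula), 0L)
  radius <- vapply(candidates, function(sp) sp$dispersal$radius_km, 0)
  wexp <- vapply(candidates, function(sp) sp$dispersal$weight_exponent, 0)
  ord <- .rank_candidate_order(waic_v, n_terms, radius)
  tab <- data.frame(
    rank = seq_len(k),
    radius_km = radius[ord],
    weight = c("equal", "inverse", "inverse-squared")[wexp[ord] + 1],
    formula = vapply(candidates[ord], function(sp) format(sp$formula), ""),
    epoch = vapply(candidates[ord], function(sp) sp$epoch, ""),
    waic = waic_v[ord],
    auc = auc_v[ord])
  attr(tab, "fits") <- fits[ord]
  attr(tab, "candidates") <- candidates[ord]
  class(tab) <- c("ranking_table", "data.frame")
  tab
}

#' @export
print.ranking_table <- function(x, n = 10L, ...) {
  cat(sprintf("ranking_table: %d candidates (top %d shown)\n",
              nrow(x), min(n, nrow(x))))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Select the best-ranked candidate
#'
#' @param table a [evaluate_candidates()] ranking.
#' @return List with the rank-1 `spec` ([candidate_spec()]),
#'   `habitat_model`, `dynamics_fit`, `waic` and `auc`.
#' @export
select_best <- function(table) {
  stopifnot(inherits(table, "ranking_table"), nrow(table) > 0)
  if (all(is.na(table$waic))) {
    stop("all candidates failed to fit; nothing to select", call. = FALSE)
  }
  fits <- attr(table, "fits")
  specs <- attr(table, "candidates")
  list(spec = specs[[1L]], habitat_model = fits[[1L]]$habitat,
       dynamics_fit = fits[[1L]]$dynamics,
       waic = table$waic[1L], auc = table$auc[1L])
}

#' Write a ranking table as CSV
#'
#' @param table a [evaluate_candidates()] ranking.
#' @param path output path.
#' @export
write_ranking <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
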
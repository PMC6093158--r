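#' Scenario bundle of future environmental tables
#'
#' A scenario group (`baseline`, `lu_only`, `cl_only` or `lucl`) holds one
#' or more member scenarios; each member maps every projection step year to
#' an [env_table()].  All members must cover the same step years.
#'
#' @param group one of `"baseline"`, `"lu_only"`, `"cl_only"`, `"lucl"`.
#' @param members named list of members; each member is a named list of
#'   [env_table()]s keyed by step year (e.g. `"2028"`, ..., `"2103"`).
#' @return A list of class `scenario_bundle`.
#' @export
scenario_bundle <- function(group = c("baseline", "lu_only", "cl_only", "lucl"),
                            members) {
  group <- match.arg(group)
  stopifnot(is.list(members), length(members) >= 1L)
  if (is.null(names(members))) {
    names(members) <- sprintf("%s_%02d", group, seq_along(members))
  }
  steps <- names(members[[1L]])
  if (is.null(steps) || length(steps) < 1L) {
    stop("each member must be a named list of env tables keyed by step year",
         call. = FALSE)
  }
  for (m in members) {
    if (!identical(names(m), steps)) {
      stop("all members must cover the same step years, in the same order",
           call. = FALSE)
    }
    for (e in m) stopifnot(inherits(e, "env_table"))
  }
  structure(list(group = group, members = members, steps = steps),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("scenario_bundle '%s': %d member(s), steps %s\n",
              x$group, length(x$members), paste(x$steps, collapse = ", ")))
  invisible(x)
}

#' Projection configuration
#'
#' @param replicates number of stochastic replicates (default 1,000).
#' @param threshold occupancy-frequency cutoff defining the potential
#'   distribution (default 0.1725, a 95%-sensitivity threshold).
#' @param seed integer seed; each replicate uses an independent derived
#'   stream, so earlier replicates are unchanged when `replicates` grows.
#' @param dispersal a [neighborhood_spec()] for the dispersal covariate.
#' @param params a [dynamics_params()] point (typically posterior medians).
#' @return A list of class `projection_config`.
#' @export
projection_config <- function(replicates = 1000L, threshold = 0.1725,
                              seed = 1L, dispersal = neighborhood_spec(100, 2),
                              params) {
  stopifnot(inherits(dispersal, "neighborhood_spec"),
            inherits(params, "dynamics_params"))
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(replicates = as.integer(replicates), threshold = threshold,
                 seed = as.integer(seed), dispersal = dispersal,
                 params = params),
            class = "projection_config")
}

#' Stochastic forward projection of occupancy under one scenario member
#'
#' Starting from the observed occupancy, each replicate advances the
#' landscape step by step: the dispersal covariate D is computed from the
#' current occupancy (the first step uses the observed field), habitat
#' suitability H from the step's environmental table, transition
#' probabilities from the parameter point, and the next occupancy is drawn
#' cell-wise Bernoulli.  Occupancy frequencies are occupied-replicate
#' counts divided by the number of replicates.
#'
#' @param model a [habitat_model()] (the suitability surface generator).
#' @param occ_start the observed [occupancy_field()] to start from.
#' @param grid the [cell_grid()].
#' @param member named list of [env_table()]s keyed by step year.
#' @param config a [projection_config()].
#' @return A list of class `projection_result`: `freq` (cells x steps
#'   matrix of occupancy frequencies), `area_km2` (potential-distribution
#'   area per step), `steps`, `replicates`, `threshold`.
#' @export
project_scenario <- function(model, occ_start, grid, member, config) {
  stopifnot(inherits(model, "habitat_model"), inherits(config, "projection_config"),
            inherits(occ_start, "occupancy_field"))
  steps <- names(member)
  if (is.null(steps) || !length(steps)) {
    stop("scenario member must be a named list of env tables keyed by step year",
         call. = FALSE)
  }
  stop_if_not_aligned(length(occ_start), nrow(grid), "occupancy", "grid")
  W <- neighbor_weights(grid, config$dispersal)
  has_ac <- !is.null(model$formula$autocov)
  W_ac <- if (has_ac) neighbor_weights(grid, model$formula$autocov)
  # H per step is fixed unless the habitat model carries an autocovariate,
  # in which case it is refreshed from the simulated occupancy each step.
  h_fixed <- if (!has_ac) {
    lapply(member, function(e) as.numeric(suitability(model, e, grid)))
  }
  n <- nrow(grid)
  counts <- matrix(0L, n, length(steps), dimnames = list(NULL, steps))
  x0 <- as.numeric(unclass(occ_start))
  for (r in seq_len(config$replicates)) {
    set.seed(derive_seed(config$seed, paste0("replicate-", r)))
    state <- x0
    for (s in seq_along(steps)) {
      d <- as.numeric(W %*% state)
      h <- if (has_ac) {
        as.numeric(suitability(model, member[[s]], grid,
                               autocov_d = as.numeric(W_ac %*% state)))
      } else h_fixed[[s]]
      q <- transition_probability(config$params, state, d, h)
      state <- stats::rbinom(n, 1L, q)
      counts[, s] <- counts[, s] + state
    }
  }
  freq <- counts / config$replicates
  areas <- apply(freq, 2, potential_area, threshold = config$threshold,
                 cell_areas = grid$area_km2)
  structure(list(freq = freq, area_km2 = areas, steps = steps,
                 replicates = config$replicates, threshold = config$threshold),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: %d replicates, threshold %.4f\n",
              x$replicates, x$threshold))
  print(round(x$area_km2, 1))
  invisible(x)
}

#' @export
plot.projection_result <- function(x, ...) {
  graphics::plot(as.numeric(x$steps), x$area_km2, type = "b",
                 xlab = "step year", ylab = "potential distribution (km^2)", ...)
  invisible(x)
}

#' Potential-distribution area
#'
#' Total area of cells whose occupancy frequency is strictly greater than
#' the threshold.
#'
#' @param frequencies occupancy frequencies in [0, 1] per cell.
#' @param threshold cutoff in (0, 1); cells must exceed it strictly.
#' @param cell_areas per-cell areas in km^2.
#' @return Area in km^2.
#' @export
potential_area <- function(frequencies, threshold, cell_areas) {
  stop_if_not_aligned(length(frequencies), length(cell_areas),
                      "frequencies", "cell areas")
  if (any(frequencies < 0 | frequencies > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  sum(cell_areas[frequencies > threshold])
}

#' Percent change of a scenario area over baseline
#'
#' @param area_scenario,area_baseline areas in km^2; baseline must be
#'   positive.
#' @return Signed percent change, rounded to one decimal.
#' @examples
#' percent_change(340.4e3, 304.2e3)  # +11.9
#' @export
percent_change <- function(area_scenario, area_baseline) {
  if (any(area_baseline <= 0)) stop("baseline area must be positive", call. = FALSE)
  round(100 * (area_scenario - area_baseline) / area_baseline, 1)
}

#' Project every member of a scenario bundle
#'
#' @param model a [habitat_model()].
#' @param occ_start starting [occupancy_field()].
#' @param grid the [cell_grid()].
#' @param bundle a [scenario_bundle()].
#' @param config a [projection_config()]; member index is folded into the
#'   seed so members are independent but reproducible.
#' @return Named list of [project_scenario()] results, one per member.
#' @export
project_bundle <- function(model, occ_start, grid, bundle, config) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  out <- vector("list", length(bundle$members))
  names(out) <- names(bundle$members)
  for (m in seq_along(bundle$members)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("member-", names(out)[m]))
    out[[m]] <- project_scenario(model, occ_start, grid,
                                 bundle$members[[m]], cfg)
  }
  out
}

#' Aggregate projection results over a scenario group
#'
#' Cell-wise mean occupancy frequency over members, and for each step the
#' mean and 2.5/97.5 percentiles of the members' potential-distribution
#' areas.
#'
#' @param results list of [project_scenario()] results (one per member).
#' @return List of class `group_summary` with `mean_freq` (cells x steps),
#'   `area_series` (data frame: `step`, `mean`, `lo95`, `hi95`),
#'   `member_areas` (members x steps matrix).
#' @export
aggregate_group <- function(results) {
  stopifnot(length(results) >= 1L)
  steps <- results[[1L]]$steps
  freq_sum <- Reduce(`+`, lapply(results, function(r) r$freq))
  areas <- do.call(rbind, lapply(results, function(r) r$area_km2))
  series <- data.frame(
    step = steps,
    mean = colMeans(areas),
    lo95 = apply(areas, 2, stats::quantile, probs = 0.025),
    hi95 = apply(areas, 2, stats::quantile, probs = 0.975))
  rownames(series) <- NULL
  structure(list(mean_freq = freq_sum / length(results),
                 area_series = series, member_areas = areas),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary over %d member(s):\n", nrow(x$member_areas)))
  print(transform(x$area_series, mean = round(mean, 1),
                  lo95 = round(lo95, 1), hi95 = round(hi95, 1)))
  invisible(x)
}

#' Write per-step occupancy frequencies / area series as CSV
#'
#' @param result a [project_scenario()] result.
#' @param grid the matching [cell_grid()].
#' @param results named list of group results from [aggregate_group()] or
#'   of member results.
#' @param path output path.
#' @name projection_io
NULL

#' @rdname projection_io
#' @export
write_projection_freq <- function(result, grid, path) {
  df <- data.frame(cell_id = grid$cell_id, result$freq, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname projection_io
#' @export
write_area_series <- function(results, path) {
  rows <- list()
  for (g in names(results)) {
    mem <- results[[g]]
    for (m in names(mem)) {
      r <- mem[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, member = m, year = r$steps, area_km2 = r$area_km2)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
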
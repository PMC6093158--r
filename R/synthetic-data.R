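#' Synthetic landscape configuration
#'
#' Parameters of the synthetic-landscape generator, which emulates the
#' statistical structure of the national 5-km survey grid: a regular
#' projected grid split into a northern "hokkaido" band and a southern
#' "other" band, spatially autocorrelated snow and slope fields with a
#' south-north snow gradient, compositional land-use proportions from a
#' softmax of correlated fields (forest-dominated, with an implicit
#' "other" remainder), and a second epoch derived from the first by a
#' snow-cover decline, urban growth around built-up cells and agricultural
#' abandonment to wasteland.
#'
#' The defaults (124 x 124 cells at 5-km spacing, ~22% Hokkaido by area,
#' 25-km correlation length, cell area 23.06 km^2, a 12-day snow-cover
#' decline between epochs) mirror the scale of the real survey grid
#' (15,256 cells covering about 351.8e3 km^2).
#'
#' @param n_rows,n_cols grid dimensions (>= 2 each).
#' @param spacing_km centroid spacing in km.
#' @param hokkaido_fraction fraction of northern rows labelled "hokkaido".
#' @param corr_length_km correlation length of the smoothed fields, km.
#' @param cell_area_km2 area of each cell, km^2.
#' @param scp_change_days mean change in snow cover period between epochs.
#' @param scp_change_sd spatial standard deviation of the snow-cover
#'   change (an autocorrelated field; larger values make the change more
#'   spatially structured).
#' @param urban_growth maximum built-up proportion gain between epochs.
#' @param abandonment_rate fraction of agriculture transferred to
#'   wasteland between epochs.
#' @param seed integer seed.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_rows = 124L, n_cols = 124L, spacing_km = 5,
                             hokkaido_fraction = 0.22, corr_length_km = 25,
                             cell_area_km2 = 23.06, scp_change_days = -12,
                             scp_change_sd = 4,
                             urban_growth = 0.03, abandonment_rate = 0.10,
                             seed = 1L) {
  if (n_rows < 2L || n_cols < 2L) {
    stop("grid dimensions must be at least 2 x 2", call. = FALSE)
  }
  if (corr_length_km <= 0) stop("correlation length must be positive", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 spacing_km = spacing_km, hokkaido_fraction = hokkaido_fraction,
                 corr_length_km = corr_length_km, cell_area_km2 = cell_area_km2,
                 scp_change_days = scp_change_days, scp_change_sd = scp_change_sd,
                 urban_growth = urban_growth,
                 abandonment_rate = abandonment_rate, seed = as.integer(seed)),
            class = "landscape_config")
}

# Standardized spatially autocorrelated field: white noise smoothed by a
# separable Gaussian kernel whose bandwidth (in cells) is the correlation
# length.  Cheap stand-in for exact Gaussian-process sampling.
.smooth_field <- function(n_rows, n_cols, corr_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  kern <- function(n) {
    k <- exp(-0.5 * outer(seq_len(n), seq_len(n), "-")^2 / corr_cells^2)
    k / rowSums(k)
  }
  f <- kern(n_rows) %*% z %*% t(kern(n_cols))
  as.numeric((f - mean(f)) / stats::sd(f))
}

#' Generate a synthetic landscape
#'
#' @param config a [landscape_config()].
#' @return List with `grid` ([cell_grid()]), `env_first` and `env_second`
#'   ([env_table()]s labelled "1978" and "2003").
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols
  n <- nr * nc
  row_i <- rep(seq_len(nr), times = nc)
  col_i <- rep(seq_len(nc), each = nr)
  x_km <- (col_i - 1) * config$spacing_km
  y_km <- (row_i - 1) * config$spacing_km
  region <- ifelse(row_i > nr * (1 - config$hokkaido_fraction), "hokkaido", "other")
  grid <- cell_grid(seq_len(n), x_km, y_km, region, config$cell_area_km2)

  set.seed(derive_seed(config$seed, "landscape"))
  corr_cells <- config$corr_length_km / config$spacing_km
  f <- replicate(9, .smooth_field(nr, nc, corr_cells), simplify = FALSE)
  y_norm <- (row_i - 1) / (nr - 1)

  # Snow increases northwards with autocorrelated local deviation.
  scp1 <- pmin(366, pmax(0, 15 + 105 * y_norm + 22 * f[[1]]))
  msd1 <- pmax(0, 0.8 * scp1 + 15 * f[[2]])
  sl <- pmax(0, 10 + 8 * f[[3]])
  # Compositional land use via softmax over five correlated fields; the
  # fifth ("other") is the implicit remainder, so fr+ws+ag+bt < 1.
  a <- cbind(fr = 1.6 + 0.8 * f[[4]], ws = -0.6 + 0.6 * f[[5]],
             ag = 0.3 + 0.9 * f[[6]], bt = -1.2 + 1.0 * f[[7]], other = 0)
  e <- exp(a)
  p <- e / rowSums(e)
  env1 <- env_table("1978", grid$cell_id, scp1, msd1,
                    p[, "fr"], p[, "ws"], p[, "ag"], p[, "bt"], sl)

  set.seed(derive_seed(config$seed, "drift"))
  scp2 <- pmin(366, pmax(0, scp1 + config$scp_change_days +
                              config$scp_change_sd * .smooth_field(nr, nc, corr_cells)))
  msd2 <- pmax(0, msd1 + 0.8 * (scp2 - scp1))
  # Urban growth proportional to existing built-up share, fed from the
  # other three classes; abandonment moves agriculture to wasteland.
  fr <- p[, "fr"]; ws <- p[, "ws"]; ag <- p[, "ag"]; bt <- p[, "bt"]
  growth <- config$urban_growth * bt / max(bt)
  pool <- fr + ws + ag
  take <- pmin(growth, pool * 0.5)
  frac <- ifelse(pool > 0, take / pool, 0)
  fr2 <- fr * (1 - frac); ws2 <- ws * (1 - frac); ag2 <- ag * (1 - frac)
  bt2 <- bt + take
  aband <- config$abandonment_rate * ag2
  ag2 <- ag2 - aband; ws2 <- ws2 + aband
  env2 <- env_table("2003", grid$cell_id, scp2, msd2, fr2, ws2, ag2, bt2, sl)
  list(grid = grid, env_first = env1, env_second = env2)
}

#' Simulate first-survey occupancy from a habitat model
#'
#' Cells are occupied independently with probability logistic(H) under the
#' supplied habitat model — the habitat GLM run in reverse as a generator.
#'
#' @param model a [habitat_model()] (no autocovariate).
#' @param env the epoch's [env_table()].
#' @param grid the [cell_grid()].
#' @param seed integer seed.
#' @param year label for the returned field.
#' @return An [occupancy_field()].
#' @export
simulate_initial_occupancy <- function(model, env, grid, seed = 1L,
                                       year = "1978") {
  h <- suitability(model, env, grid)
  set.seed(derive_seed(seed, "occupancy-initial"))
  occupancy_field(stats::rbinom(nrow(grid), 1L, stats::plogis(as.numeric(h))),
                  year)
}

#' Simulate second-survey occupancy from the transition model
#'
#' @param params a [dynamics_params()].
#' @param occ_first first-survey [occupancy_field()].
#' @param d dispersal covariate vector in [0, 1].
#' @param h habitat suitability (log odds) vector.
#' @param seed integer seed.
#' @param year label for the returned field.
#' @return An [occupancy_field()].
#' @export
simulate_transition <- function(params, occ_first, d, h, seed = 1L,
                                year = "2003") {
  q <- transition_probability(params, unclass(occ_first), d, h)
  set.seed(derive_seed(seed, "occupancy-transition"))
  occupancy_field(stats::rbinom(length(q), 1L, q), year)
}

#' Trend configuration for scenario generation
#'
#' @param scp_step_days snow-cover-period change per 25-year step (days;
#'   negative = warming).
#' @param abandon_rate fraction of (agriculture + built-up) moved to
#'   wasteland per step under land abandonment.
#' @param n_members members per scenario group, named vector over
#'   `baseline`, `lu_only`, `cl_only`, `lucl`.  The default 1/9/4/36
#'   mirrors the scenario families the projection design targets
#'   (`lucl` is the cross of the `lu_only` and `cl_only` members).
#' @return A list of class `trend_config`.
#' @export
trend_config <- function(scp_step_days = -5, abandon_rate = 0.05,
                         n_members = c(baseline = 1L, lu_only = 9L,
                                       cl_only = 4L, lucl = 36L)) {
  stopifnot(all(c("baseline", "lu_only", "cl_only", "lucl") %in% names(n_members)))
  if (n_members[["lucl"]] != n_members[["lu_only"]] * n_members[["cl_only"]]) {
    stop("lucl member count must equal lu_only x cl_only (the scenario cross)",
         call. = FALSE)
  }
  structure(list(scp_step_days = scp_step_days, abandon_rate = abandon_rate,
                 n_members = n_members),
            class = "trend_config")
}

# Member strength multipliers spread around 1 so members within a group
# differ in trend velocity (0.5x to 1.5x the base trend).
.member_multipliers <- function(k) {
  if (k == 1L) return(1)
  seq(0.5, 1.5, length.out = k)
}

# Apply cumulative trends to an env table for one step count.
.trend_env <- function(env, grid, steps_done, cl_mult, lu_mult, trends, epoch) {
  scp <- env$scp; msd <- env$msd
  fr <- env$fr; ws <- env$ws; ag <- env$ag; bt <- env$bt
  if (!is.null(cl_mult)) {
    d_scp <- cl_mult * trends$scp_step_days * steps_done
    scp_new <- pmin(366, pmax(0, scp + d_scp))
    msd <- pmax(0, msd + 0.8 * (scp_new - scp))
    scp <- scp_new
  }
  if (!is.null(lu_mult)) {
    r <- 1 - (1 - pmin(1, lu_mult * trends$abandon_rate))^steps_done
    moved <- r * (ag + bt)
    ws <- ws + moved
    ag <- ag * (1 - r); bt <- bt * (1 - r)
  }
  env_table(epoch, env$cell_id, scp, msd, fr, ws, ag, bt, env$sl)
}

#' Generate the four scenario bundles
#'
#' Builds `baseline` (environment held at the starting epoch), `lu_only`
#' (land abandonment only: agriculture and built-up transfer to wasteland,
#' mass-conserving; snow untouched), `cl_only` (snow-cover decline only)
#' and `lucl` (the full cross of the land-use and climate members) over
#' the four 25-year projection steps.
#'
#' @param env_start the starting [env_table()] (typically the second
#'   survey epoch).
#' @param grid the [cell_grid()].
#' @param trends a [trend_config()].
#' @param steps step-year labels.
#' @return Named list of four [scenario_bundle()]s.
#' @export
generate_scenarios <- function(env_start, grid, trends = trend_config(),
                               steps = c("2028", "2053", "2078", "2103")) {
  stopifnot(inherits(env_start, "env_table"), inherits(trends, "trend_config"))
  nm <- trends$n_members
  cl_mults <- .member_multipliers(nm[["cl_only"]])
  lu_mults <- .member_multipliers(nm[["lu_only"]])
  member <- function(cl_mult, lu_mult) {
    out <- lapply(seq_along(steps), function(s) {
      .trend_env(env_start, grid, s, cl_mult, lu_mult, trends, steps[s])
    })
    names(out) <- steps
    out
  }
  baseline <- scenario_bundle("baseline", list(baseline_01 = member(NULL, NULL)))
  lu <- lapply(lu_mults, function(m) member(NULL, m))
  names(lu) <- sprintf("lu_%02d", seq_along(lu))
  cl <- lapply(cl_mults, function(m) member(m, NULL))
  names(cl) <- sprintf("cl_%02d", seq_along(cl))
  lucl <- list()
  for (i in seq_along(lu_mults)) for (j in seq_along(cl_mults)) {
    lucl[[sprintf("lucl_%02d_%02d", i, j)]] <- member(cl_mults[j], lu_mults[i])
  }
  list(baseline = baseline,
       lu_only = scenario_bundle("lu_only", lu),
       cl_only = scenario_bundle("cl_only", cl),
       lucl = scenario_bundle("lucl", lucl))
}

#' Tiny deterministic fixture bundle
#'
#' A hand-checkable landscape of 68 cells: an 8 x 8 block at 5-km spacing
#' (top two rows "hokkaido"), a detached three-cell strip whose middle and
#' far cells sit 5 and 10 km from its first cell (so the distance-weighted
#' neighborhood occupancy of that cell is exactly 0.5, 2/3 or 0.8 under
#' weight exponents 0, 1, 2 when the near cell is occupied and the far one
#' empty), and one isolated cell with no neighbor within 100 km.
#' Environments are smooth deterministic functions of the coordinates;
#' occupancy in the first survey is deterministic (suitability above the
#' block median, plus the strip's near cell), and the second survey is a
#' seeded draw from the transition model at the reference parameters.
#'
#' @return List with `grid`, `env_first`, `env_second`, `occ_first`,
#'   `occ_second`.
#' @export
make_fixture <- function() {
  row_i <- rep(1:8, times = 8); col_i <- rep(1:8, each = 8)
  x <- c((col_i - 1) * 5, 1000, 1005, 1010, 3000)
  y <- c((row_i - 1) * 5, 0, 0, 0, 0)
  region <- c(ifelse(row_i > 6, "hokkaido", "other"), rep("other", 4))
  n <- length(x)
  grid <- cell_grid(seq_len(n), x, y, region)
  scp <- pmin(366, pmax(0, 20 + 2.2 * y + 8 * sin(x / 12)))
  scp[65:68] <- c(40, 45, 50, 60)
  msd <- 0.8 * scp
  sl <- 8 + 6 * abs(sin(x / 9 + y / 13))
  fr <- 0.40 + 0.12 * sin(x / 15 + 1); ws <- 0.08 + 0.04 * cos(y / 11)
  ag <- 0.18 + 0.08 * sin(y / 17); bt <- 0.05 + 0.03 * cos(x / 21)
  env1 <- env_table("1978", grid$cell_id, scp, msd, fr, ws, ag, bt, sl)
  scp2 <- pmax(0, scp - 12)
  msd2 <- pmax(0, msd - 9.6)
  ab <- 0.1 * ag
  env2 <- env_table("2003", grid$cell_id, scp2, msd2, fr, ws + ab,
                    ag - ab, bt, sl)
  model <- sika_habitat_model()
  h1 <- as.numeric(suitability(model, env1, grid))
  # seeded Bernoulli occupancy on the block (a deterministic threshold
  # would be perfectly separable and unfittable); strip and isolated
  # cells hand-set for the worked neighborhood examples
  set.seed(derive_seed(7L, "fixture-occupancy"))
  occ1 <- rep(0L, n)
  occ1[1:64] <- stats::rbinom(64, 1L, stats::plogis(h1[1:64]))
  occ1[66] <- 1L # strip near cell occupied; focal (65) and far (67) empty
  occ1[67] <- 0L; occ1[65] <- 0L; occ1[68] <- 0L
  occ_first <- occupancy_field(occ1, "1978")
  d <- suppressWarnings(
    neighborhood_occupancy(occ_first, grid, neighborhood_spec(25, 2)))
  h2 <- as.numeric(suitability(model, env2, grid))
  # seed chosen so both strata contain both outcomes (the transition model
  # stays fittable on the fixture)
  occ_second <- simulate_transition(sika_dynamics_params(), occ_first, d, h2,
                                    seed = 19L)
  list(grid = grid, env_first = env1, env_second = env2,
       occ_first = occ_first, occ_second = occ_second)
}
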
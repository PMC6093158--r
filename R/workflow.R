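#' Validate landscape input files
#'
#' Checks the three CSV dialects rule by rule without stopping at the
#' first violation: cell table (unique ids, finite coordinates, positive
#' areas, known regions), environment table (finite values, snow-cover
#' period in [0, 366], non-negative depth and slope, land-use proportions
#' in [0, 1] with closure <= 1) and occupancy table (values 0/1).
#'
#' @param paths named list with any of `cells`, `env`, `occupancy`.
#' @return A data frame with columns `table`, `cell_id`, `rule`; zero rows
#'   when every invariant holds.
#' @export
validate_inputs <- function(paths) {
  bad <- list()
  note <- function(table, cell_id, rule) {
    bad[[length(bad) + 1L]] <<- data.frame(table = table,
                                           cell_id = as.character(cell_id),
                                           rule = rule)
  }
  if (!is.null(paths$cells)) {
    df <- utils::read.csv(paths$cells)
    dup <- df$cell_id[duplicated(df$cell_id)]
    for (id in unique(dup)) note("cells", id, "cell ids must be unique")
    ok <- is.finite(df$x_km) & is.finite(df$y_km)
    for (id in df$cell_id[!ok]) note("cells", id, "coordinates must be finite")
    ok <- is.finite(df$area_km2) & df$area_km2 > 0
    for (id in df$cell_id[!ok]) note("cells", id, "area_km2 must be positive")
    ok <- df$region %in% c("hokkaido", "other")
    for (id in df$cell_id[!ok]) note("cells", id, "region must be hokkaido/other")
  }
  if (!is.null(paths$env)) {
    df <- utils::read.csv(paths$env)
    num <- c("scp", "msd", "fr", "ws", "ag", "bt", "sl")
    fin <- rowSums(!is.finite(as.matrix(df[num]))) > 0
    for (id in df$cell_id[fin]) note("env", id, "environmental values must be finite")
    ok <- !fin & df$scp >= 0 & df$scp <= 366
    for (id in df$cell_id[!ok & !fin]) note("env", id, "scp must lie in [0, 366]")
    for (v in c("msd", "sl")) {
      blame <- !fin & df[[v]] < 0
      for (id in df$cell_id[blame]) note("env", id, sprintf("%s must be non-negative", v))
    }
    for (v in c("fr", "ws", "ag", "bt")) {
      blame <- !fin & (df[[v]] < 0 | df[[v]] > 1)
      for (id in df$cell_id[blame]) note("env", id, sprintf("%s must lie in [0, 1]", v))
    }
    closure <- df$fr + df$ws + df$ag + df$bt
    blame <- !fin & closure > 1 + 1e-9
    for (id in df$cell_id[blame]) {
      note("env", id, "land-use proportions fr+ws+ag+bt must sum to at most 1")
    }
  }
  if (!is.null(paths$occupancy)) {
    df <- utils::read.csv(paths$occupancy)
    blame <- !df$present %in% c(0, 1)
    for (id in df$cell_id[blame]) note("occupancy", id, "present must be 0 or 1")
  }
  if (!length(bad)) {
    return(data.frame(table = character(0), cell_id = character(0),
                      rule = character(0)))
  }
  do.call(rbind, bad)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole workflow on one configuration: load (or
#' synthesize) the landscape, fit habitat models, evaluate and select the
#' candidate grid by WAIC, decompose suitability change, project the four
#' scenario groups forward, and summarize.  Every artifact is written under
#' `out_dir` and listed, with its MD5 checksum, in a JSON manifest so
#' reruns with the same configuration and seed are verifiably identical.
#'
#' @param config a list with elements
#'   \describe{
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{seed}{master seed; every stage derives its own stream.}
#'     \item{paths}{optional named list (`cells`, `env`, `occupancy`) of
#'       input CSVs; when absent a synthetic landscape is generated.}
#'     \item{landscape}{[landscape_config()] for synthetic generation
#'       (default a 30 x 30 grid).}
#'     \item{candidates}{list of [candidate_spec()] to evaluate (default: a
#'       small sweep of the reference formula over both epochs and two
#'       dispersal specs).}
#'     \item{mcmc}{list with `chains`, `iterations`, `burnin`.}
#'     \item{projection}{list with `replicates`, `threshold` (optional:
#'       derived from a 95% sensitivity rule when absent), `trends` (a
#'       [trend_config()]).}
#'   }
#' @return The manifest (invisibly): list with `seed`, `artifacts` (name,
#'   path, md5) and headline `results`.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% stop("config$out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  mcmc <- config$mcmc %||% list()
  chains <- mcmc$chains %||% 3L
  iterations <- mcmc$iterations %||% 400L
  burnin <- mcmc$burnin %||% 100L
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  artifacts <- list()
  add_artifact <- function(name, path) {
    artifacts[[length(artifacts) + 1L]] <<- list(
      name = name, path = path, md5 = unname(tools::md5sum(path)))
  }

  # --- data -----------------------------------------------------------
  data <- stage("data", {
    if (!is.null(config$paths)) {
      for (p in unlist(config$paths)) {
        if (!file.exists(p)) stop(sprintf("input file '%s' does not exist", p))
      }
      report <- validate_inputs(config$paths)
      if (nrow(report)) {
        stop(sprintf("%d input invariant violation(s); first: %s (cell %s)",
                     nrow(report), report$rule[1], report$cell_id[1]))
      }
      grid <- read_cell_grid(config$paths$cells)
      envs <- read_env_tables(config$paths$env, grid)
      occs <- read_occupancy_fields(config$paths$occupancy, grid)
      list(grid = grid, env_first = envs[[1]], env_second = envs[[2]],
           occ_first = occs[[1]], occ_second = occs[[2]])
    } else {
      lc <- config$landscape %||% landscape_config(n_rows = 30L, n_cols = 30L,
                                                   seed = derive_seed(seed, "landscape"))
      land <- generate_landscape(lc)
      model <- sika_habitat_model()
      occ1 <- simulate_initial_occupancy(model, land$env_first, land$grid,
                                         seed = derive_seed(seed, "occ1"))
      d <- suppressWarnings(neighborhood_occupancy(
        occ1, land$grid, neighborhood_spec(100, 2)))
      h2 <- as.numeric(suitability(model, land$env_second, land$grid))
      occ2 <- simulate_transition(sika_dynamics_params(), occ1, d, h2,
                                  seed = derive_seed(seed, "occ2"))
      list(grid = land$grid, env_first = land$env_first,
           env_second = land$env_second, occ_first = occ1, occ_second = occ2)
    }
  })
  write_cell_grid(data$grid, file.path(out_dir, "cells.csv"))
  add_artifact("cells", file.path(out_dir, "cells.csv"))
  write_env_table(list(data$env_first, data$env_second),
                  file.path(out_dir, "env.csv"))
  add_artifact("env", file.path(out_dir, "env.csv"))
  write_occupancy(list(data$occ_first, data$occ_second), data$grid,
                  file.path(out_dir, "occupancy.csv"))
  add_artifact("occupancy", file.path(out_dir, "occupancy.csv"))

  env_list <- list(data$env_first, data$env_second)
  names(env_list) <- c(attr(data$env_first, "epoch"), attr(data$env_second, "epoch"))

  # --- candidate evaluation and selection -----------------------------
  candidates <- config$candidates %||% {
    f <- habitat_formula(TRUE, "scp", TRUE)
    build_candidate_grid(formulas = list(f), epochs = names(env_list),
                         radii_km = c(25, 50), weight_exponents = 2)
  }
  ranking <- stage("select", {
    evaluate_candidates(candidates, data$occ_first, data$occ_second, env_list,
                        data$grid, chains = chains, iterations = iterations,
                        burnin = burnin, seed = derive_seed(seed, "select"))
  })
  write_ranking(ranking, file.path(out_dir, "ranking.csv"))
  add_artifact("ranking", file.path(out_dir, "ranking.csv"))
  best <- select_best(ranking)
  write_habitat_model(best$habitat_model, file.path(out_dir, "habitat_model.json"))
  add_artifact("habitat_model", file.path(out_dir, "habitat_model.json"))
  write_dynamics_draws(best$dynamics_fit, file.path(out_dir, "dynamics_draws.csv"))
  add_artifact("dynamics_draws", file.path(out_dir, "dynamics_draws.csv"))
  write_dynamics_summary(best$dynamics_fit, file.path(out_dir, "dynamics_summary.json"))
  add_artifact("dynamics_summary", file.path(out_dir, "dynamics_summary.json"))

  # --- suitability-change decomposition -------------------------------
  change <- stage("decompose", {
    decompose_change(best$habitat_model, data$env_first, data$env_second,
                     data$grid)
  })
  utils::write.csv(change$delta, file.path(out_dir, "suitability_change.csv"),
                   row.names = FALSE)
  add_artifact("suitability_change", file.path(out_dir, "suitability_change.csv"))

  # --- projection -----------------------------------------------------
  proj_cfg <- config$projection %||% list()
  params <- coef(best$dynamics_fit)
  threshold <- proj_cfg$threshold %||% stage("threshold", {
    q <- transition_probability(params, data$occ_first,
                                suppressWarnings(neighborhood_occupancy(
                                  data$occ_first, data$grid, best$spec$dispersal)),
                                as.numeric(suitability(best$habitat_model,
                                                       env_list[[best$spec$epoch]],
                                                       data$grid)))
    sensitivity_threshold(q[unclass(data$occ_second) == 1L], 0.95)
  })
  results <- stage("project", {
    trends <- proj_cfg$trends %||% trend_config(
      n_members = c(baseline = 1L, lu_only = 3L, cl_only = 2L, lucl = 6L))
    bundles <- generate_scenarios(data$env_second, data$grid, trends)
    pc <- projection_config(replicates = proj_cfg$replicates %||% 200L,
                            threshold = threshold,
                            seed = derive_seed(seed, "project"),
                            dispersal = best$spec$dispersal, params = params)
    lapply(bundles, function(b) project_bundle(best$habitat_model,
                                               data$occ_second, data$grid,
                                               b, pc))
  })
  write_area_series(results, file.path(out_dir, "areas.csv"))
  add_artifact("areas", file.path(out_dir, "areas.csv"))

  # --- summary --------------------------------------------------------
  groups <- lapply(results, aggregate_group)
  final_step <- utils::tail(groups$baseline$area_series$step, 1)
  base_area <- utils::tail(groups$baseline$area_series$mean, 1)
  summary <- list(
    seed = seed, threshold = threshold,
    waic = best$waic, auc = best$auc,
    selected = format(best$spec),
    pct_cells_suitability_increase = change$pct_increased,
    chisq_change = if (!is.null(change$chisq)) unname(change$chisq$statistic),
    area_2103 = lapply(groups, function(g) utils::tail(g$area_series$mean, 1)),
    pct_change_2103 = lapply(groups, function(g) {
      percent_change(utils::tail(g$area_series$mean, 1), base_area)
    }))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  add_artifact("summary", file.path(out_dir, "summary.json"))

  manifest <- list(seed = seed, final_step = final_step,
                   artifacts = artifacts, results = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
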
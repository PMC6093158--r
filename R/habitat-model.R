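#' Candidate habitat-model formula
#'
#' A habitat-suitability model is a logistic regression of presence/absence
#' on up to three covariate blocks plus an optional autocovariate:
#' \itemize{
#'   \item land use (`include_lu`): forest, wasteland, agriculture (with a
#'     quadratic term capturing the unimodal response), built-up;
#'   \item climate (`climate`): either snow cover period (`"scp"`) or
#'     maximum snow depth (`"msd"`), never both (they are collinear), each
#'     entering with a region main effect and a climate-by-region
#'     interaction so the snow response may differ between Hokkaido and the
#'     other islands (Hokkaido is the reference level);
#'   \item topography (`include_topo`): slope inclination;
#'   \item an optional autologistic term (`autocov`): neighborhood
#'     occupancy at radius 10 or 25 km.
#' }
#'
#' @param include_lu logical, include the land-use block.
#' @param climate `"none"`, `"scp"` or `"msd"`.
#' @param include_topo logical, include slope inclination.
#' @param autocov `NULL` or a [neighborhood_spec()] with radius 10 or 25 km.
#' @return A list of class `habitat_formula`.
#' @export
habitat_formula <- function(include_lu = TRUE, climate = c("none", "scp", "msd"),
                            include_topo = TRUE, autocov = NULL) {
  climate <- match.arg(climate)
  if (!is.null(autocov)) {
    stopifnot(inherits(autocov, "neighborhood_spec"))
    if (!autocov$radius_km %in% c(10, 25)) {
      stop("autocovariate radius must be 10 or 25 km", call. = FALSE)
    }
  }
  structure(list(include_lu = isTRUE(include_lu), climate = climate,
                 include_topo = isTRUE(include_topo), autocov = autocov),
            class = "habitat_formula")
}

#' @export
format.habitat_formula <- function(x, ...) {
  parts <- character(0)
  if (x$include_lu) parts <- c(parts, "LU")
  if (x$climate != "none") parts <- c(parts, sprintf("CL[%s]", toupper(x$climate)))
  if (x$include_topo) parts <- c(parts, "TOPO")
  if (!is.null(x$autocov)) {
    parts <- c(parts, sprintf("AC(%g km, p=%g)", x$autocov$radius_km,
                              x$autocov$weight_exponent))
  }
  paste("~", if (length(parts)) paste(parts, collapse = " + ") else "1")
}

#' @export
print.habitat_formula <- function(x, ...) {
  cat("habitat_formula:", format(x), "\n")
  invisible(x)
}

# Coefficient names implied by a formula, in design order.
.habitat_term_names <- function(formula) {
  nm <- "intercept"
  if (formula$climate == "scp") nm <- c(nm, "scp", "rgn_other", "scp_x_rgn")
  if (formula$climate == "msd") nm <- c(nm, "msd", "rgn_other", "msd_x_rgn")
  if (formula$include_lu) nm <- c(nm, "fr", "ws", "ag", "ag2", "bt")
  if (formula$include_topo) nm <- c(nm, "sl")
  if (!is.null(formula$autocov)) nm <- c(nm, "autocov")
  nm
}

.n_habitat_terms <- function(formula) length(.habitat_term_names(formula)) - 1L

# Design matrix for a habitat formula.  Covariates enter unstandardized
# (scp in days, land-use proportions in [0,1], slope in degrees).
.habitat_design <- function(formula, env, grid, autocov_d = NULL) {
  stopifnot(inherits(env, "env_table"), inherits(grid, "cell_grid"))
  stop_if_not_aligned(nrow(env), nrow(grid), "env table", "grid")
  n <- nrow(grid)
  cols <- list(intercept = rep(1, n))
  if (formula$climate != "none") {
    cv <- formula$climate
    if (is.null(env[[cv]])) stop(sprintf("env table lacks covariate '%s'", cv), call. = FALSE)
    rgn <- as.numeric(grid$region == "other")
    cols[[cv]] <- env[[cv]]
    cols$rgn_other <- rgn
    cols[[paste0(cv, "_x_rgn")]] <- env[[cv]] * rgn
  }
  if (formula$include_lu) {
    for (cv in c("fr", "ws", "ag", "bt")) {
      if (is.null(env[[cv]])) stop(sprintf("env table lacks covariate '%s'", cv), call. = FALSE)
    }
    cols$fr <- env$fr; cols$ws <- env$ws
    cols$ag <- env$ag; cols$ag2 <- env$ag^2; cols$bt <- env$bt
  }
  if (formula$include_topo) {
    if (is.null(env$sl)) stop("env table lacks covariate 'sl'", call. = FALSE)
    cols$sl <- env$sl
  }
  if (!is.null(formula$autocov)) {
    if (is.null(autocov_d)) {
      stop("formula includes an autocovariate but no autocov_d vector was supplied",
           call. = FALSE)
    }
    stop_if_not_aligned(length(autocov_d), n, "autocov_d", "grid")
    cols$autocov <- as.numeric(autocov_d)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Enumerate candidate habitat formulae
#'
#' All combinations of the land-use block (in/out), climate variable
#' (none / snow cover period / maximum snow depth) and topography block
#' (in/out) give 12 base formulae; models containing both snow variables
#' are excluded by construction.  With `with_autocov = TRUE` each base
#' formula is additionally crossed with the 6 autocovariate options
#' (radius 10 or 25 km, weight exponent 0/1/2) plus "no autocovariate",
#' giving 84.
#'
#' @param with_autocov logical; cross with autocovariate options?
#' @return List of [habitat_formula()] objects (length 12 or 84).
#' @export
enumerate_habitat_formulas <- function(with_autocov = FALSE) {
  base <- list()
  for (lu in c(TRUE, FALSE)) for (cl in c("none", "scp", "msd")) {
    for (topo in c(TRUE, FALSE)) {
      base <- c(base, list(habitat_formula(lu, cl, topo)))
    }
  }
  if (!with_autocov) return(base)
  acs <- list(NULL)
  for (r in c(10, 25)) for (p in c(0, 1, 2)) {
    acs <- c(acs, list(neighborhood_spec(r, p)))
  }
  out <- list()
  for (f in base) for (ac in acs) {
    out <- c(out, list(habitat_formula(f$include_lu, f$climate, f$include_topo, ac)))
  }
  out
}

#' Habitat-suitability model object
#'
#' Builds a `habitat_model` from a formula and a named coefficient vector
#' (e.g. externally reported estimates); [fit_habitat()] builds one from
#' data by maximum likelihood.  The coefficient names must match the
#' formula's terms exactly (see Details of [habitat_formula()]).
#'
#' @param formula a [habitat_formula()].
#' @param coefficients named numeric vector; names from
#'   `c("intercept","scp","msd","rgn_other","scp_x_rgn","msd_x_rgn",
#'   "fr","ws","ag","ag2","bt","sl","autocov")` as implied by the formula.
#' @param se optional named standard errors.
#' @param n,loglik optional fit metadata.
#' @return A list of class `habitat_model`.
#' @export
habitat_model <- function(formula, coefficients, se = NULL, n = NA_integer_,
                          loglik = NA_real_) {
  stopifnot(inherits(formula, "habitat_formula"))
  nm <- .habitat_term_names(formula)
  if (!setequal(names(coefficients), nm)) {
    stop(sprintf("coefficient names must be exactly {%s}", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  coefficients <- coefficients[nm]
  if (!all(is.finite(coefficients))) stop("coefficients must be finite", call. = FALSE)
  structure(list(formula = formula, coefficients = coefficients,
                 se = if (!is.null(se)) se[nm] else NULL,
                 n = n, loglik = loglik),
            class = "habitat_model")
}

#' Fit a habitat-suitability logistic model
#'
#' Maximum-likelihood logistic regression of first-survey occupancy on the
#' environmental covariates selected by `formula`.  When the formula
#' includes an autocovariate it is computed from `occ` itself (the
#' occupancy being modelled) unless `autocov_d` is supplied.
#'
#' @param occ an [occupancy_field()] (the training survey year).
#' @param env the matching [env_table()].
#' @param grid the [cell_grid()].
#' @param formula a [habitat_formula()].
#' @param autocov_d optional precomputed autocovariate vector.
#' @return A [habitat_model()] with coefficients, standard errors,
#'   log-likelihood and n.
#' @export
fit_habitat <- function(occ, env, grid, formula, autocov_d = NULL) {
  stopifnot(inherits(occ, "occupancy_field"), inherits(formula, "habitat_formula"))
  stop_if_not_aligned(length(occ), nrow(grid), "occupancy", "grid")
  y <- as.integer(unclass(occ))
  if (all(y == 0L) || all(y == 1L)) {
    stop("response is all-absence or all-presence; the logistic model is not identifiable",
         call. = FALSE)
  }
  if (!is.null(formula$autocov) && is.null(autocov_d)) {
    autocov_d <- neighborhood_occupancy(occ, grid, formula$autocov)
  }
  X <- .habitat_design(formula, env, grid, autocov_d)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  rhs <- if (ncol(df) > 1L) paste(colnames(X)[-1], collapse = " + ") else "1"
  fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)),
                    family = stats::binomial(), data = df)
  cf <- stats::coef(fit)
  names(cf)[1] <- "intercept"
  if (!fit$converged || any(!is.finite(cf)) || max(abs(cf)) > 50) {
    stop(paste("habitat model did not converge cleanly (possible complete separation);",
               sprintf("largest |coefficient| = %.1f", max(abs(cf)))), call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(cf)
  habitat_model(formula, cf, se = se, n = length(y),
                loglik = as.numeric(stats::logLik(fit)))
}

#' @export
coef.habitat_model <- function(object, ...) object$coefficients

#' @export
logLik.habitat_model <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("habitat_model:", format(x$formula), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.habitat_model <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients)
  if (!is.null(object$se)) {
    tab$se <- object$se
    tab$lower95 <- tab$estimate - 1.96 * tab$se
    tab$upper95 <- tab$estimate + 1.96 * tab$se
  }
  structure(list(formula = object$formula, coefficients = tab,
                 n = object$n, loglik = object$loglik),
            class = "summary.habitat_model")
}

#' @export
print.summary.habitat_model <- function(x, ...) {
  cat("Habitat suitability model", format(x$formula), "\n")
  if (!is.na(x$n)) cat(sprintf("n = %d, log-likelihood = %.2f\n", x$n, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Habitat-suitability surface (log odds)
#'
#' Evaluates the linear predictor of a habitat model on an epoch's
#' environmental table.  The result is the habitat suitability H on the
#' log-odds scale (not passed through the logistic function); apply
#' `plogis()` for occurrence probabilities.
#'
#' @param model a [habitat_model()].
#' @param env an [env_table()] for the epoch of interest.
#' @param grid the [cell_grid()].
#' @param autocov_d autocovariate vector, required when the model formula
#'   has one.
#' @return Numeric vector of class `suitability_surface` (log odds) with an
#'   `epoch` attribute.
#' @export
suitability <- function(model, env, grid, autocov_d = NULL) {
  stopifnot(inherits(model, "habitat_model"))
  X <- .habitat_design(model$formula, env, grid, autocov_d)
  h <- as.numeric(X %*% model$coefficients)
  structure(h, epoch = attr(env, "epoch"), class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("suitability_surface: epoch %s, %d cells, log-odds range [%.2f, %.2f]\n",
              attr(x, "epoch") %||% "?", length(x), min(x), max(x)))
  invisible(x)
}

#' @export
predict.habitat_model <- function(object, env, grid, autocov_d = NULL,
                                  type = c("link", "response"), ...) {
  type <- match.arg(type)
  h <- suitability(object, env, grid, autocov_d)
  if (type == "response") stats::plogis(as.numeric(h)) else h
}

#' Decompose suitability change into climate and land-use fractions
#'
#' Evaluates the habitat linear predictor under both epochs' environments
#' and splits the per-cell change dH = H(second) - H(first) into the
#' climate block (snow variable and its region interaction) and the
#' land-use block (fr, ws, ag, ag^2, bt).  Because the linear predictor has
#' no climate-by-land-use products and the topographic, region and
#' autocovariate terms are held fixed, dH equals the two fractions' sum
#' exactly.  Cells are then cross-classified (suitability increased vs
#' decreased x land-use- vs climate-dominated) and association is tested by
#' a continuity-corrected chi-square test.
#'
#' Ties: cells with dH = 0 count as "increased", cells with equal absolute
#' fractions count as land-use-dominated (both are measure-zero for
#' continuous covariates).
#'
#' @param model a [habitat_model()].
#' @param env_first,env_second [env_table()]s of the two epochs, aligned to
#'   `grid`.
#' @param grid the [cell_grid()].
#' @param autocov_d autocovariate vector (held fixed across epochs), if the
#'   formula has one.
#' @return A list of class `suitability_change`: `delta` (data frame with
#'   `dh_total`, `dh_climate`, `dh_landuse` per cell), `counts` (2x2 matrix,
#'   rows LU>CL / LU<CL, columns increased / decreased), `chisq` (the
#'   `htest`), `pct_increased`.
#' @export
decompose_change <- function(model, env_first, env_second, grid, autocov_d = NULL) {
  stopifnot(inherits(model, "habitat_model"))
  if (!identical(env_first$cell_id, env_second$cell_id) ||
      !identical(env_first$cell_id, grid$cell_id)) {
    stop("epoch tables and grid are misaligned (cell ids differ)", call. = FALSE)
  }
  X1 <- .habitat_design(model$formula, env_first, grid, autocov_d)
  X2 <- .habitat_design(model$formula, env_second, grid, autocov_d)
  beta <- model$coefficients
  dX <- X2 - X1
  cl_terms <- intersect(c("scp", "msd", "scp_x_rgn", "msd_x_rgn"), colnames(dX))
  lu_terms <- intersect(c("fr", "ws", "ag", "ag2", "bt"), colnames(dX))
  block <- function(terms) {
    if (!length(terms)) return(rep(0, nrow(dX)))
    as.numeric(dX[, terms, drop = FALSE] %*% beta[terms])
  }
  dh_climate <- block(cl_terms)
  dh_landuse <- block(lu_terms)
  dh_total <- as.numeric(X2 %*% beta) - as.numeric(X1 %*% beta)
  increased <- dh_total >= 0
  lu_dom <- abs(dh_landuse) >= abs(dh_climate)
  counts <- matrix(c(sum(lu_dom & increased), sum(lu_dom & !increased),
                     sum(!lu_dom & increased), sum(!lu_dom & !increased)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("LU>CL", "LU<CL"),
                                   c("increased", "decreased")))
  chisq <- if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) {
    stats::chisq.test(counts, correct = TRUE)
  } else NULL
  structure(list(delta = data.frame(cell_id = grid$cell_id,
                                    dh_total = dh_total,
                                    dh_climate = dh_climate,
                                    dh_landuse = dh_landuse),
                 counts = counts, chisq = chisq,
                 pct_increased = 100 * mean(increased)),
            class = "suitability_change")
}

#' @export
print.suitability_change <- function(x, ...) {
  cat(sprintf("suitability change over %d cells: %.1f%% increased\n",
              nrow(x$delta), x$pct_increased))
  print(x$counts)
  if (!is.null(x$chisq)) {
    cat(sprintf("continuity-corrected chi-square = %.1f (df = %d, p %s)\n",
                unname(x$chisq$statistic), unname(x$chisq$parameter),
                format.pval(x$chisq$p.value)))
  }
  invisible(x)
}

#' Export / import habitat coefficients as JSON
#'
#' @param model a [habitat_model()].
#' @param path JSON file path.
#' @return `read_habitat_model` returns a [habitat_model()].
#' @name habitat_io
NULL

#' @rdname habitat_io
#' @export
write_habitat_model <- function(model, path) {
  stopifnot(inherits(model, "habitat_model"))
  obj <- list(formula = list(include_lu = model$formula$include_lu,
                             climate = model$formula$climate,
                             include_topo = model$formula$include_topo,
                             autocov = if (!is.null(model$formula$autocov)) {
                               list(radius_km = model$formula$autocov$radius_km,
                                    weight_exponent = model$formula$autocov$weight_exponent)
                             }),
              coefficients = as.list(model$coefficients),
              n = model$n, loglik = model$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname habitat_io
#' @export
read_habitat_model <- function(path) {
  obj <- jsonlite::read_json(path)
  ac <- if (!is.null(obj$formula$autocov)) {
    neighborhood_spec(obj$formula$autocov$radius_km, obj$formula$autocov$weight_exponent)
  }
  f <- habitat_formula(obj$formula$include_lu, obj$formula$climate,
                       obj$formula$include_topo, ac)
  habitat_model(f, unlist(obj$coefficients),
                n = obj$n %||% NA_integer_, loglik = obj$loglik %||% NA_real_)
}
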
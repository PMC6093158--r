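#' Gridded landscape: cell geometry
#'
#' Constructs and validates the cell table of a gridded landscape: one row
#' per cell with a unique integer id, projected centroid coordinates in km,
#' a region flag separating Hokkaido from the other three main islands, and
#' the cell area in km^2.  The default area of 23.06 km^2 corresponds to a
#' 3'45" x 2'30" (about 5 x 5 km) standard mesh cell.
#'
#' @param cell_id integer vector of unique cell ids.
#' @param x_km,y_km numeric centroid coordinates on a planar projection, km.
#' @param region character or factor, each element `"hokkaido"` or `"other"`.
#' @param area_km2 positive cell areas in km^2; recycled if scalar.
#' @return A `data.frame` of class `cell_grid` with columns `cell_id`,
#'   `x_km`, `y_km`, `region`, `area_km2`.
#' @examples
#' g <- cell_grid(1:4, x_km = c(0, 5, 0, 5), y_km = c(0, 0, 5, 5),
#'                region = "other")
#' nrow(g)
#' @export
cell_grid <- function(cell_id, x_km, y_km, region, area_km2 = 23.06) {
  n <- length(cell_id)
  if (n < 1L) stop("a cell grid needs at least one cell", call. = FALSE)
  cell_id <- as.integer(cell_id)
  if (anyDuplicated(cell_id)) stop("cell ids must be unique", call. = FALSE)
  x_km <- as.numeric(x_km); y_km <- as.numeric(y_km)
  stop_if_not_aligned(length(x_km), n, "x_km", "cell_id")
  stop_if_not_aligned(length(y_km), n, "y_km", "cell_id")
  if (!all(is.finite(x_km)) || !all(is.finite(y_km))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  region <- rep_len(as.character(region), n)
  if (!all(region %in% c("hokkaido", "other"))) {
    stop("region must be 'hokkaido' or 'other'", call. = FALSE)
  }
  area_km2 <- rep_len(as.numeric(area_km2), n)
  if (!all(is.finite(area_km2)) || any(area_km2 <= 0)) {
    stop("area_km2 must be positive and finite", call. = FALSE)
  }
  structure(
    data.frame(cell_id = cell_id, x_km = x_km, y_km = y_km,
               region = region, area_km2 = area_km2),
    class = c("cell_grid", "data.frame"))
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %d cells, total area %.1f km^2 (%.1f%% hokkaido)\n",
              nrow(x), sum(x$area_km2),
              100 * mean(x$region == "hokkaido")))
  invisible(x)
}

#' Per-epoch environmental covariate table
#'
#' One row per grid cell holding the environmental covariates of one epoch:
#' snow cover period `scp` (days per year), maximum snow depth `msd` (cm),
#' land-use proportions `fr` (forest), `ws` (wasteland), `ag` (agriculture),
#' `bt` (built-up), and slope inclination `sl` (degrees).  The four land-use
#' proportions may sum to less than one; the remainder is an implicit
#' "other" category.
#'
#' @param epoch label of the epoch (e.g. `"1978"`).
#' @param cell_id integer cell ids matching a [cell_grid()].
#' @param scp,msd,fr,ws,ag,bt,sl numeric covariate vectors.
#' @return A `data.frame` of class `env_table` with an `epoch` attribute.
#' @export
env_table <- function(epoch, cell_id, scp, msd, fr, ws, ag, bt, sl) {
  n <- length(cell_id)
  vals <- list(scp = scp, msd = msd, fr = fr, ws = ws, ag = ag, bt = bt, sl = sl)
  for (nm in names(vals)) {
    vals[[nm]] <- as.numeric(vals[[nm]])
    if (length(vals[[nm]]) == 1L) vals[[nm]] <- rep(vals[[nm]], n)
    stop_if_not_aligned(length(vals[[nm]]), n, nm, "cell_id")
    if (!all(is.finite(vals[[nm]]))) {
      stop(sprintf("environmental variable '%s' contains non-finite values", nm),
           call. = FALSE)
    }
  }
  if (any(vals$scp < 0 | vals$scp > 366)) {
    stop("scp must lie in [0, 366] days", call. = FALSE)
  }
  if (any(vals$msd < 0)) stop("msd must be non-negative", call. = FALSE)
  if (any(vals$sl < 0)) stop("sl must be non-negative", call. = FALSE)
  for (nm in c("fr", "ws", "ag", "bt")) {
    if (any(vals[[nm]] < -1e-9 | vals[[nm]] > 1 + 1e-9)) {
      stop(sprintf("land-use proportion '%s' must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  closure <- vals$fr + vals$ws + vals$ag + vals$bt
  if (any(closure > 1 + 1e-9)) {
    stop("land-use proportions fr + ws + ag + bt exceed 1 in some cells",
         call. = FALSE)
  }
  out <- data.frame(cell_id = as.integer(cell_id))
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  structure(out, epoch = as.character(epoch),
            class = c("env_table", "data.frame"))
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: epoch %s, %d cells\n", attr(x, "epoch"), nrow(x)))
  print(summary(as.data.frame(x)[-1]))
  invisible(x)
}

#' Binary occupancy of one survey year
#'
#' @param present binary 0/1 vector over grid cells (presence = 1).
#' @param year label of the survey year.
#' @return An integer vector of class `occupancy_field` with a `year`
#'   attribute.
#' @export
occupancy_field <- function(present, year) {
  x <- as.integer(present)
  if (length(x) < 1L || anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop("occupancy values must all be 0 or 1", call. = FALSE)
  }
  structure(x, year = as.character(year), class = "occupancy_field")
}

#' @export
print.occupancy_field <- function(x, ...) {
  cat(sprintf("occupancy_field: year %s, %d cells, prevalence %.3f\n",
              attr(x, "year"), length(x), mean(unclass(x))))
  invisible(x)
}

#' Distance-weighted neighborhood specification
#'
#' Defines the neighborhood used for the dispersal covariate D (and for
#' autocovariates in habitat models): a radius in km and a distance-decay
#' exponent p, with weights w = d^(-p).  p = 0 weights all neighbors
#' equally, p = 1 by inverse distance, p = 2 by inverse squared distance.
#'
#' @param radius_km positive neighborhood radius in km.
#' @param weight_exponent distance-decay exponent, one of 0, 1, 2.
#' @return A list of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(radius_km, weight_exponent = 0) {
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop("radius_km must be a single positive number", call. = FALSE)
  }
  if (!weight_exponent %in% c(0, 1, 2)) {
    stop("weight_exponent must be 0 (equal), 1 (inverse) or 2 (inverse-squared)",
         call. = FALSE)
  }
  structure(list(radius_km = as.numeric(radius_km),
                 weight_exponent = as.numeric(weight_exponent)),
            class = "neighborhood_spec")
}

#' @export
format.neighborhood_spec <- function(x, ...) {
  wt <- c("equal", "inverse", "inverse-squared")[x$weight_exponent + 1]
  sprintf("%g km, %s", x$radius_km, wt)
}

#' @export
print.neighborhood_spec <- function(x, ...) {
  cat("neighborhood_spec:", format(x), "\n")
  invisible(x)
}

# Directed neighbor pairs within `radius` on planar km coordinates,
# computed by bucketing cells into radius-sized blocks so only the 3 x 3
# block neighborhood of each cell is searched.  Returns (i, j, d) triplets
# with i != j and 0 < d <= radius; symmetric by construction.
.neighbor_pairs <- function(x, y, radius) {
  n <- length(x)
  bx <- floor(x / radius); by <- floor(y / radius)
  bx <- bx - min(bx); by <- by - min(by)
  nbx <- max(bx) + 1
  nby <- max(by) + 1
  key <- bx + by * nbx
  blocks <- split(seq_len(n), key)
  block_xy <- lapply(names(blocks), function(k) {
    k <- as.numeric(k)
    c(k %% nbx, k %/% nbx)
  })
  names(block_xy) <- names(blocks)
  ii <- list(); jj <- list(); dd <- list(); out <- 0L
  for (k in names(blocks)) {
    focal <- blocks[[k]]
    bxy <- block_xy[[k]]
    for (dxb in -1:1) for (dyb in -1:1) {
      nbx_i <- bxy[1] + dxb; nby_i <- bxy[2] + dyb
      if (nbx_i < 0 || nbx_i >= nbx || nby_i < 0 || nby_i >= nby) next
      nk <- as.character(nbx_i + nby_i * nbx)
      cand <- blocks[[nk]]
      if (is.null(cand)) next
      dx <- outer(x[focal], x[cand], "-")
      dy <- outer(y[focal], y[cand], "-")
      d <- sqrt(dx * dx + dy * dy)
      keep <- which(d <= radius & d > 0)
      if (length(keep)) {
        out <- out + 1L
        ii[[out]] <- focal[(keep - 1L) %% length(focal) + 1L]
        jj[[out]] <- cand[(keep - 1L) %/% length(focal) + 1L]
        dd[[out]] <- d[keep]
      }
    }
  }
  list(i = unlist(ii) %||% integer(0),
       j = unlist(jj) %||% integer(0),
       d = unlist(dd) %||% numeric(0))
}

#' Neighbor index of a cell grid
#'
#' For every cell, the ids of and Euclidean centroid distances to all other
#' cells within `radius_km`.  The focal cell is excluded from its own
#' neighborhood.  Distances are planar Euclidean on the projected km
#' coordinates.
#'
#' @param grid a [cell_grid()].
#' @param radius_km positive neighborhood radius in km.
#' @return A list of class `neighbor_index` with elements `neighbors`
#'   (list of integer vectors of row indices into `grid`), `cell_ids`
#'   (list of the corresponding cell ids), `distances` (list of numeric
#'   vectors, km) and `radius_km`.
#' @examples
#' g <- cell_grid(1:2, c(0, 5), c(0, 0), "other")
#' build_neighbor_index(g, 10)$distances
#' @export
build_neighbor_index <- function(grid, radius_km) {
  stopifnot(inherits(grid, "cell_grid"))
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  n <- nrow(grid)
  prs <- .neighbor_pairs(grid$x_km, grid$y_km, radius_km)
  nb <- rep(list(integer(0)), n)
  ds <- rep(list(numeric(0)), n)
  if (length(prs$i)) {
    ord <- order(prs$i, prs$d)
    sp_j <- split(prs$j[ord], prs$i[ord])
    sp_d <- split(prs$d[ord], prs$i[ord])
    idx <- as.integer(names(sp_j))
    nb[idx] <- sp_j
    ds[idx] <- sp_d
  }
  structure(list(neighbors = nb,
                 cell_ids = lapply(nb, function(v) grid$cell_id[v]),
                 distances = ds,
                 radius_km = radius_km),
            class = "neighbor_index")
}

#' Sparse neighborhood weight matrix
#'
#' Row-normalized sparse matrix W such that `W %*% x` gives the
#' distance-weighted mean of `x` over each cell's neighborhood (weights
#' d^(-p)).  Rows of cells with no neighbor within the radius are all zero.
#' Precompute this once when the same neighborhood is applied to many
#' occupancy vectors (model selection sweeps, projection replicates).
#'
#' @param grid a [cell_grid()].
#' @param spec a [neighborhood_spec()].
#' @return A `dgCMatrix` with rows summing to 1 (or 0 for isolated cells).
#' @export
neighbor_weights <- function(grid, spec) {
  stopifnot(inherits(grid, "cell_grid"), inherits(spec, "neighborhood_spec"))
  n <- nrow(grid)
  prs <- .neighbor_pairs(grid$x_km, grid$y_km, spec$radius_km)
  w <- if (spec$weight_exponent == 0) rep(1, length(prs$d)) else prs$d^(-spec$weight_exponent)
  W <- Matrix::sparseMatrix(i = prs$i, j = prs$j, x = w, dims = c(n, n))
  rs <- Matrix::rowSums(W)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  methods::as(Matrix::Diagonal(x = inv) %*% W, "CsparseMatrix")
}

#' Neighborhood occupancy (dispersal covariate D)
#'
#' The distance-weighted proportion of occupied cells within the
#' neighborhood of each cell: D_i = sum_j w_ij X_j / sum_j w_ij with
#' w_ij = d_ij^(-p), focal cell excluded.  D lies in [0, 1] and serves as
#' the dispersal covariate of the transition model and as the autocovariate
#' of autologistic habitat models.  Cells with no neighbor inside the
#' radius get D = 0 (with a warning).
#'
#' @param occ an [occupancy_field()] aligned to `grid`.
#' @param grid a [cell_grid()].
#' @param spec a [neighborhood_spec()].
#' @param weights optional precomputed [neighbor_weights()] matrix.
#' @return Numeric vector D in [0, 1] over cells.
#' @examples
#' g <- cell_grid(1:3, c(0, 5, 10), c(0, 0, 0), "other")
#' occ <- occupancy_field(c(0, 1, 0), "1978")
#' neighborhood_occupancy(occ, g, neighborhood_spec(10, 2))
#' @export
neighborhood_occupancy <- function(occ, grid, spec, weights = NULL) {
  stopifnot(inherits(occ, "occupancy_field"), inherits(grid, "cell_grid"))
  stop_if_not_aligned(length(occ), nrow(grid), "occupancy", "grid")
  W <- weights %||% neighbor_weights(grid, spec)
  d <- as.numeric(W %*% as.numeric(unclass(occ)))
  isolated <- Matrix::rowSums(W != 0) == 0
  if (any(isolated)) {
    warning(sprintf("%d cell(s) have no neighbor within %g km; D set to 0",
                    sum(isolated), spec$radius_km), call. = FALSE)
    d[isolated] <- 0
  }
  d
}

#' Temporal inverse-distance interpolation
#'
#' Interpolates a covariate observed in a few years to a target year by
#' inverse-distance weighting in time: weights 1/|target - year| over all
#' observations.  Exact at observed years; always within the observed
#' range.
#'
#' @param years numeric vector of observation years.
#' @param values numeric vector of observed values.
#' @param target_year year to interpolate to.
#' @return Interpolated value.
#' @examples
#' interpolate_timeseries(c(1976, 1987), c(0.20, 0.42), 1977)  # 0.22
#' @export
interpolate_timeseries <- function(years, values, target_year) {
  if (length(years) < 1L) stop("at least one observation is required", call. = FALSE)
  stop_if_not_aligned(length(values), length(years), "values", "years")
  if (!all(is.finite(values))) stop("observed values must be finite", call. = FALSE)
  hit <- which(years == target_year)
  if (length(hit)) return(values[hit[1L]])
  w <- 1 / abs(target_year - years)
  sum(w * values) / sum(w)
}

#' Read and write landscape tables
#'
#' CSV readers/writers for the three table dialects: cells
#' (`cell_id,x_km,y_km,region,area_km2`), environment
#' (`cell_id,epoch,scp,msd,fr,ws,ag,bt,sl`; one file may hold several
#' epochs) and occupancy (`cell_id,year,present`).
#'
#' @param path file path.
#' @param grid,env,occ objects to write; for `write_env_table` a single
#'   [env_table()] or list of them; for `write_occupancy` a single
#'   [occupancy_field()] or list of them.
#' @return Readers return the validated objects (`read_env_tables` and
#'   `read_occupancy_fields` return named lists keyed by epoch/year, with
#'   rows ordered as in `grid`).
#' @name landscape_io
NULL

#' @rdname landscape_io
#' @export
read_cell_grid <- function(path) {
  df <- utils::read.csv(path)
  cell_grid(df$cell_id, df$x_km, df$y_km, df$region, df$area_km2)
}

#' @rdname landscape_io
#' @export
write_cell_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname landscape_io
#' @export
read_env_tables <- function(path, grid) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$epoch), function(sub) {
    m <- match(grid$cell_id, sub$cell_id)
    if (anyNA(m)) stop(sprintf("env table in %s is missing cells present in the grid", path),
                       call. = FALSE)
    sub <- sub[m, ]
    env_table(sub$epoch[1], sub$cell_id, sub$scp, sub$msd,
              sub$fr, sub$ws, sub$ag, sub$bt, sub$sl)
  })
  out
}

#' @rdname landscape_io
#' @export
write_env_table <- function(env, path) {
  if (inherits(env, "env_table")) env <- list(env)
  rows <- lapply(env, function(e) {
    cbind(data.frame(cell_id = e$cell_id, epoch = attr(e, "epoch")),
          as.data.frame(e)[c("scp", "msd", "fr", "ws", "ag", "bt", "sl")])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname landscape_io
#' @export
read_occupancy_fields <- function(path, grid) {
  df <- utils::read.csv(path)
  lapply(split(df, df$year), function(sub) {
    m <- match(grid$cell_id, sub$cell_id)
    if (anyNA(m)) stop(sprintf("occupancy table in %s is missing cells present in the grid", path),
                       call. = FALSE)
    occupancy_field(sub$present[m], sub$year[1])
  })
}

#' @rdname landscape_io
#' @export
write_occupancy <- function(occ, grid, path) {
  if (inherits(occ, "occupancy_field")) occ <- list(occ)
  rows <- lapply(occ, function(o) {
    data.frame(cell_id = grid$cell_id, year = attr(o, "year"),
               present = as.integer(unclass(o)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
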
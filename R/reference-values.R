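#' Reference estimates from the Japan-wide sika deer range-change analysis
#'
#' Published point estimates used throughout the package as defaults for
#' the synthetic-data generator and as worked-example anchors: the
#' best habitat-suitability model (land use + snow cover period with
#' region interaction + slope; Hokkaido the reference region), the
#' posterior medians of the six transition parameters, the observed
#' 2x2 classification of suitability change (rows: land-use- vs
#' climate-dominated; columns: suitability increased vs decreased over
#' 15,256 cells), and the reported potential-distribution areas in 2103
#' under the four scenario groups (km^2; ranges for multi-member groups).
#'
#' The habitat model and dynamics parameters are shipped as JSON fixtures
#' under `inst/extdata/` and read back through the package's own I/O.
#'
#' @return `sika_habitat_model()`: a [habitat_model()];
#'   `sika_dynamics_params()`: a [dynamics_params()];
#'   `sika_change_counts()`: a 2x2 integer matrix;
#'   `sika_area_2103_km2()`: named list of areas.
#' @name sika_reference
NULL

#' @rdname sika_reference
#' @export
sika_habitat_model <- function() {
  read_habitat_model(system.file("extdata", "sika_habitat_model.json",
                                 package = "rangedyn", mustWork = TRUE))
}

#' @rdname sika_reference
#' @export
sika_dynamics_params <- function() {
  obj <- jsonlite::read_json(system.file("extdata", "sika_dynamics_params.json",
                                         package = "rangedyn", mustWork = TRUE))
  dynamics_params(obj$phi0, obj$phi_d, obj$phi_h,
                  obj$gam0, obj$gam_d, obj$gam_h)
}

#' @rdname sika_reference
#' @export
sika_change_counts <- function() {
  matrix(c(220L, 4011L, 10705L, 320L), nrow = 2, byrow = TRUE,
         dimnames = list(c("LU>CL", "LU<CL"), c("increased", "decreased")))
}

#' @rdname sika_reference
#' @export
sika_area_2103_km2 <- function() {
  list(baseline = 304.2e3,
       lu_only = c(308.5e3, 312.1e3),
       cl_only = c(313.7e3, 334.0e3),
       lucl = c(318.3e3, 340.4e3))
}
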
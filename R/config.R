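#' Default run configuration
#'
#' Nested list mirroring the parameter objects: sections `geometry`,
#' `oxygen`, `radiobiology`, `protocol`, `cohort`, `output`, plus a
#' top-level `seed`. The protocol defaults to 2 Gy daily (weekends off) to
#' a total of 20 Gy from day 21, the reference conventional arm.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    geometry = list(grid_side = 600L, pixel_size_um = 15,
                    tumour_radius_px = 50L, normal_fraction = 0.20,
                    vessel_density = 0.038, n_layers = 3L,
                    cell_area_um2 = 225),
    oxygen = list(sigma = 2.4, s = 0.02356, cap = 0.05,
                  hypoxia_threshold = 0.002),
    radiobiology = list(alpha = 0.0441, beta = 0.0898, hrf_m = 2.804,
                        hrf_K = 0.001076,
                        # surrogate endothelial LQ values; replace with
                        # fitted clonogenic coefficients when available
                        alpha_ec = 0.28, beta_ec = 0.045,
                        leak_factor = 1.5, vessel_death_threshold = 6,
                        vessel_death_max = 35, arrest_slope = 9),
    protocol = list(frac_dose = 2, total_dose = 20, interval_days = 1L,
                    start_day = 21L, weekends_off = TRUE,
                    horizon_days = 80L),
    cohort = list(n_mice = 100L, scenario = "dlo_vperf_vdeath"),
    output = list(dir = "radca-out", snapshots = TRUE)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration field: ", full)
    if (is.list(defaults[[nm]]) && !is.null(user[[nm]])) {
      if (!is.list(user[[nm]]))
        stop("configuration section ", full, " must be a mapping")
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown fields are rejected (they usually indicate a typo); missing
#' fields take the [default_config()] values. Required protocol fields
#' (`frac_dose`, `total_dose`) must be present in the file.
#'
#' @param path YAML file path.
#' @return Validated nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  for (fld in c("frac_dose", "total_dose"))
    if (is.null(user$protocol[[fld]]))
      stop("configuration is missing required field: protocol.", fld)
  cfg <- .merge_config(default_config(), user)
  # instantiate parameter objects now so invalid values fail at read time
  config_params(cfg)
  cfg
}

#' Instantiate parameter objects from a configuration list
#'
#' @param cfg Configuration list (see [default_config()]).
#' @return List with elements `geom`, `ox`, `radio`, `prot`.
#' @export
config_params <- function(cfg) {
  list(geom = do.call(geometry_params, cfg$geometry),
       ox = do.call(oxygen_params, cfg$oxygen),
       radio = do.call(radiobiology_params, cfg$radiobiology),
       prot = do.call(protocol, cfg$protocol))
}
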
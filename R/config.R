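#' Default model configuration
#'
#' Returns the full set of tunable constants used across the package, as a
#' nested list. Every value can be overridden either programmatically
#' (`tlrhm_config(radiation = list(par_fraction = 0.45))`) or from a YAML file
#' via [read_config()]. The defaults are the values used throughout the
#' package documentation and tests.
#'
#' Sections:
#' \describe{
#'   \item{radiation}{`par_fraction` (PAR / global shortwave, 0.47),
#'     `umol_per_j` (photon content of PAR, 4.55 umol/J), `absorptance`
#'     (leaf PAR absorptance, 0.9), `diffuse_poly` (clearness-index
#'     polynomial for the daily diffuse fraction, evaluated lowest order
#'     first), `diffuse_clip` (bounds the diffuse fraction).}
#'   \item{two_leaf}{`omega_defaults` (clumping index per vegetation type),
#'     `cos_beta` (mean leaf-sun cosine, spherical leaf-angle value 0.5),
#'     `scattering` (include the multiple-scattering term).}
#'   \item{temperature}{`tp_method` ("sine" daytime-mean of a
#'     sunrise-to-afternoon sinusoid, or "mean" for (tmax+tmin)/2),
#'     `peak_lag_h` (hours from solar noon to the temperature maximum).}
#'   \item{vpd}{`vpd_max`, `vpd_min` (Pa) of the linear downregulation ramp.}
#' }
#'
#' @param ... named sections whose entries override the defaults.
#' @return Nested list of configuration values.
#' @export
#' @examples
#' cfg <- tlrhm_config()
#' cfg$radiation$par_fraction
tlrhm_config <- function(...) {
  cfg <- list(
    radiation = list(
      par_fraction = 0.47,
      umol_per_j   = 4.55,
      absorptance  = 0.9,
      # daily diffuse fraction vs clearness index R = Rg/Ra,
      # polynomial used in the sunlit/shaded GPP literature
      diffuse_poly = c(0.7527, 3.8453, -16.316, 18.962, -7.0802),
      diffuse_clip = c(0.13, 1)
    ),
    two_leaf = list(
      omega_defaults = c(ENF = 0.6, DBF = 0.8, GRA = 0.9, EBF = 0.8),
      cos_beta = 0.5,
      scattering = TRUE
    ),
    temperature = list(
      tp_method  = "sine",
      peak_lag_h = 1.8
    ),
    vpd = list(
      vpd_max = 4500,
      vpd_min = 650
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML key-value file whose sections override [tlrhm_config()]
#' defaults. Unknown keys raise an error so typos do not silently fall back
#' to defaults.
#'
#' @param path path to a YAML file.
#' @return Nested configuration list as from [tlrhm_config()].
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  base <- tlrhm_config()
  for (sec in names(user)) {
    if (!sec %in% c(names(base), "ek", "run")) {
      stop("unknown configuration section: ", sec)
    }
    if (sec %in% names(base)) {
      bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
      if (length(bad)) {
        stop("unknown key(s) in section '", sec, "': ", paste(bad, collapse = ", "))
      }
      base[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      base[[sec]] <- user[[sec]]
    }
  }
  base
}

#' Default clumping index for a vegetation type
#'
#' @param vegetation_type one of "ENF", "DBF", "GRA", "EBF".
#' @param config configuration list, see [tlrhm_config()].
#' @return Clumping index (dimensionless, 0-1].
#' @export
default_omega <- function(vegetation_type, config = tlrhm_config()) {
  om <- config$two_leaf$omega_defaults
  if (!vegetation_type %in% names(om)) {
    stop("unknown vegetation type: ", vegetation_type,
         " (expected one of ", paste(names(om), collapse = ", "), ")")
  }
  unname(om[[vegetation_type]])
}
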
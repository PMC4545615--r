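## Constants the study fixes, and the reference-phantom placeholders it
## leaves open. Units are part of the field names.

.CONFIG_DEFAULTS <- list(
  calibration_MBq_per_count = 6.23e-6,
  attenuation_cm_inv        = 0.13,
  cranium_rbm_fraction      = 0.119,
  rbm_to_blood_ratio        = 1.0,
  alpha_over_beta_Gy        = 10,
  repair_rate_mu_per_h      = 0.46,
  n_histories               = 1e6,
  rng_seed                  = 1,
  rbm_mass_g                = 1170,
  s_rbm_self_mGy_per_MBq_h  = NA_real_,   # derived from rbm_mass_g when absent
  s_rbm_from_remainder_mGy_per_MBq_h = 1.1e-4,
  photon_cutoff_MeV         = 0.02,
  lung_max_g_cm3            = 0.5,
  bone_min_g_cm3            = 1.2,
  density_floor_g_cm3       = 0.05)

.CONFIG_SLOT_MAP <- c(
  calibration_MBq_per_count = "calibrationMBqPerCount",
  attenuation_cm_inv        = "attenuationCmInv",
  cranium_rbm_fraction      = "craniumRbmFraction",
  rbm_to_blood_ratio        = "rbmToBloodRatio",
  alpha_over_beta_Gy        = "alphaOverBetaGy",
  repair_rate_mu_per_h      = "repairRateMuPerH",
  n_histories               = "nHistories",
  rng_seed                  = "rngSeed",
  rbm_mass_g                = "rbmMassG",
  s_rbm_self_mGy_per_MBq_h  = "sRbmSelfMGyPerMBqH",
  s_rbm_from_remainder_mGy_per_MBq_h = "sRbmRemainderMGyPerMBqH",
  photon_cutoff_MeV         = "photonCutoffMeV",
  lung_max_g_cm3            = "lungMaxGCm3",
  bone_min_g_cm3            = "boneMinGCm3",
  density_floor_g_cm3       = "densityFloorGCm3")

## Marrow self S-value from the 177Lu mean beta energy with absorbed
## fraction 1 over the configured marrow mass: a transparent
## reference-phantom placeholder, in mGy per MBq h.
.deriveSelfSValue <- function(rbm_mass_g, beta_mean_MeV = 0.1333) {
  joule_per_MeV <- 1.602176634e-13
  decays_per_MBq_h <- 3.6e9
  beta_mean_MeV * joule_per_MeV * decays_per_MBq_h / (rbm_mass_g / 1000) * 1000
}

#' Build a dosimetry configuration
#'
#' Returns the study constants with any overrides applied. Defaults are the
#' fixed values of the serial-imaging protocol (calibration factor 6.23e-6
#' MBq per count, broad-beam attenuation 0.13 1/cm, cranium marrow fraction
#' 0.119, marrow-to-blood ratio 1, alpha/beta = 10 Gy, repair rate 0.46 1/h,
#' 1e6 Monte Carlo histories) plus reference-phantom placeholders for the
#' marrow mass (1170 g) and S-values. When no self S-value is supplied it is
#' derived from the 177Lu mean beta energy over the configured marrow mass.
#'
#' @param ... overrides by config key, e.g. \code{n_histories = 1000}.
#'   Unknown keys are an error.
#' @return A validated \linkS4class{DosimetryConfig}.
#' @examples
#' cfg <- dosimetryConfig()
#' cfg@calibrationMBqPerCount   # 6.23e-6
#' @export
dosimetryConfig <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  vals <- .CONFIG_DEFAULTS
  for (k in names(over)) {
    v <- over[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("config key '%s' must be a single finite number", k))
    vals[[k]] <- as.numeric(v)
  }
  if (is.na(vals$s_rbm_self_mGy_per_MBq_h))
    vals$s_rbm_self_mGy_per_MBq_h <- .deriveSelfSValue(vals$rbm_mass_g)
  for (k in names(vals))
    if (!is.na(vals[[k]]) && k != "rng_seed" && vals[[k]] <= 0)
      stop(sprintf("config key '%s' must be positive (got %g)", k, vals[[k]]))
  args <- setNames(vals, .CONFIG_SLOT_MAP[names(vals)])
  do.call(new, c(list("DosimetryConfig"), args))
}

#' Load a dosimetry configuration from YAML
#'
#' Reads a flat YAML mapping of config keys (see
#' \code{\link{dosimetryConfig}}); absent keys take their defaults, unknown
#' keys are rejected. Loading is idempotent:
#' \code{loadConfig(dumpConfig(cfg))} reproduces \code{cfg}.
#'
#' @param path YAML file path.
#' @return A validated \linkS4class{DosimetryConfig}.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  if (!is.list(y)) stop("config must be a YAML mapping")
  dosimetryConfig(y)
}

#' Write a configuration to YAML
#'
#' @param config a \linkS4class{DosimetryConfig}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
dumpConfig <- function(config, path) {
  keys <- names(.CONFIG_SLOT_MAP)
  vals <- lapply(keys, function(k) slot(config, .CONFIG_SLOT_MAP[[k]]))
  yaml::write_yaml(setNames(vals, keys), path, precision = 15L)
  invisible(path)
}
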
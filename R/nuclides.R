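#' Load a nuclide from the bundled decay-data file
#'
#' Decay data are versioned package data, not hard-coded constants: the
#' bundled file carries half-lives, photon lines (energy in MeV, yield per
#' decay) and beta data compiled from reference decay tables. 177Lu uses
#' local beta deposition (mean beta range well below the 4.795 mm voxel);
#' 90Y is a pure beta emitter transported along straight
#' continuous-slowing-down paths sampled from its spectrum shape.
#'
#' @param name nuclide name as listed in the data file ("Lu-177", "Y-90").
#' @param file optional alternative decay-data YAML.
#' @return A \linkS4class{Nuclide}.
#' @examples
#' lu <- loadNuclide("Lu-177")
#' decayConstantPerH(lu)
#' @export
loadNuclide <- function(name,
                        file = system.file("extdata", "nuclides.yaml",
                                           package = "voxdose")) {
  y <- yaml::read_yaml(file)
  if (is.null(y$nuclides[[name]]))
    stop("nuclide not in decay-data file: ", name)
  d <- y$nuclides[[name]]
  lines <- d$photon_lines
  pl <- if (length(lines))
    do.call(rbind, lapply(lines, as.numeric))
  else
    matrix(numeric(0), ncol = 2)
  colnames(pl) <- c("energy_MeV", "yield_per_decay")
  new("Nuclide", name = name, halfLifeH = d$half_life_h,
      photonLines = pl, betaMeanEnergyMeV = d$beta_mean_energy_MeV,
      betaYield = d$beta_yield,
      betaTransport = if (identical(d$beta_transport, "csda")) "csda" else "local",
      betaEndpointMeV = if (is.null(d$beta_endpoint_MeV)) 0 else d$beta_endpoint_MeV,
      daughterZ = if (is.null(d$daughter_Z)) 0 else d$daughter_Z)
}

#' Allowed-shape beta spectrum
#'
#' Unnormalised allowed-transition beta spectrum
#' \eqn{N(E) \propto F(Z,E)\, p W (Q - E)^2} with the nonrelativistic Fermi
#' Coulomb correction \eqn{F = 2\pi\eta / (1 - e^{-2\pi\eta})},
#' \eqn{\eta = Z \alpha W / p} (energies in units of the electron rest mass).
#' Used to sample 90Y beta energies for transport; its mean is checked
#' against the bundled reference mean energy.
#'
#' @param energyMeV kinetic energies at which to evaluate (MeV).
#' @param endpointMeV spectrum endpoint energy (MeV).
#' @param daughterZ atomic number of the daughter nucleus.
#' @return Unnormalised spectral density at \code{energyMeV}.
#' @export
betaSpectrumShape <- function(energyMeV, endpointMeV, daughterZ) {
  mec2 <- 0.51099895
  alpha <- 1 / 137.035999
  W <- energyMeV / mec2 + 1          # total energy, units of me c^2
  p <- sqrt(pmax(W^2 - 1, 0))        # momentum
  Q <- endpointMeV / mec2
  E <- energyMeV / mec2
  out <- numeric(length(energyMeV))
  ok <- energyMeV > 0 & energyMeV < endpointMeV & p > 0
  eta <- daughterZ * alpha * W[ok] / p[ok]
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  out[ok] <- fermi * p[ok] * W[ok] * (Q - E[ok])^2
  out
}

## Inverse-CDF table for beta energy sampling: column 1 = u in [0,1],
## column 2 = kinetic energy (MeV).
.betaInverseCdf <- function(nuclide, n = 512L) {
  if (nuclide@betaEndpointMeV <= 0)
    stop("nuclide has no tabulated beta spectrum shape")
  e <- seq(1e-4, nuclide@betaEndpointMeV - 1e-6, length.out = 4096L)
  dens <- betaSpectrumShape(e, nuclide@betaEndpointMeV, nuclide@daughterZ)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  u <- seq(0, 1, length.out = n)
  cbind(u, approx(c(0, cdf), c(0, e), xout = u, ties = "ordered")$y)
}

#' Mean energy of the sampled beta spectrum
#'
#' @param nuclide a \linkS4class{Nuclide} with a spectrum shape.
#' @return Mean kinetic energy (MeV) of the allowed-shape spectrum.
#' @export
betaSpectrumMeanMeV <- function(nuclide) {
  e <- seq(1e-4, nuclide@betaEndpointMeV - 1e-6, length.out = 4096L)
  dens <- betaSpectrumShape(e, nuclide@betaEndpointMeV, nuclide@daughterZ)
  sum(e * dens) / sum(dens)
}

## Electron CSDA range in water-equivalent medium, g/cm^2, by the classic
## empirical range-energy relation (valid ~0.01 to 2.5 MeV).
.csdaRangeGCm2 <- function(energyMeV) {
  0.412 * energyMeV^(1.265 - 0.0954 * log(energyMeV))
}

## Range-energy table for transport: energies (MeV) and ranges (g/cm^2),
## monotone, used for forward lookup and inversion in the engine.
.rangeTable <- function(emax = 2.5, n = 512L) {
  e <- exp(seq(log(1e-3), log(emax), length.out = n))
  cbind(e, .csdaRangeGCm2(e))
}

## Photon attenuation tables from the bundled data file, as the list the
## engine expects: per material, log-energy grid, log(mu/rho), photo fraction.
.attenuationTables <- function(file = system.file("extdata",
                                                  "photon_attenuation.yaml",
                                                  package = "voxdose")) {
  y <- yaml::read_yaml(file)
  eg <- as.numeric(y$energy_MeV)
  mats <- c("soft_tissue", "lung", "bone")
  lapply(setNames(mats, mats), function(m) {
    list(log_e = log(eg),
         log_mu_rho = log(as.numeric(y$materials[[m]]$mu_rho_cm2_g)),
         photo_fraction = as.numeric(y$materials[[m]]$photo_fraction))
  })
}
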
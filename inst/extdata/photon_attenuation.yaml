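# Photon interaction data, version 1.
# Mass attenuation coefficients (cm^2/g) on an energy grid (MeV), coherent
# scattering excluded, compiled at the percent level from standard photon
# cross-section compilations (NIST XCOM style).
# photo_fraction = photoelectric / (photoelectric + incoherent) at each energy.
# Lung shares the soft-tissue composition (density differs, composition not).
version: 1
energy_MeV: [0.02, 0.03, 0.05, 0.08, 0.10, 0.15, 0.20, 0.30, 0.50, 1.00]
materials:
  soft_tissue:
    mu_rho_cm2_g:   [0.770, 0.350, 0.214, 0.179, 0.168, 0.149, 0.136, 0.118, 0.0966, 0.0706]
    photo_fraction: [0.690, 0.410, 0.135, 0.034, 0.017, 0.005, 0.002, 0.001, 0.000,  0.000]
  lung:
    mu_rho_cm2_g:   [0.770, 0.350, 0.214, 0.179, 0.168, 0.149, 0.136, 0.118, 0.0966, 0.0706]
    photo_fraction: [0.690, 0.410, 0.135, 0.034, 0.017, 0.005, 0.002, 0.001, 0.000,  0.000]
  bone:
    mu_rho_cm2_g:   [3.60, 1.20, 0.410, 0.220, 0.183, 0.146, 0.130, 0.110, 0.0899, 0.0657]
    photo_fraction: [0.950, 0.850, 0.550, 0.250, 0.140, 0.050, 0.025, 0.010, 0.004, 0.001]
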
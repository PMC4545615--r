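# Decay data, version 1.
# Half-lives in hours; photon energies in MeV, yields per decay.
# Emission values compiled from ICRP-107 / MIRD-style reference decay tables.
# Only the two photon lines used for 177Lu imaging windows are transported;
# weaker lines (< 0.3% yield) and x-rays are folded into the neglect budget.
version: 1
nuclides:
  Lu-177:
    half_life_h: 161.04          # 6.71 d
    beta_mean_energy_MeV: 0.1333
    beta_yield: 1.0
    beta_transport: local        # mean beta range << 4.795 mm voxel
    photon_lines:
      - [0.11295, 0.0620]
      - [0.20837, 0.1036]
  Y-90:
    half_life_h: 63.84           # 2.66 d
    beta_mean_energy_MeV: 0.9337 # reference mean; spectrum sampled from shape below
    beta_yield: 1.0
    beta_transport: csda         # range of order 1 cm: transported, not local
    beta_endpoint_MeV: 2.2801
    daughter_Z: 40
    photon_lines: []
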
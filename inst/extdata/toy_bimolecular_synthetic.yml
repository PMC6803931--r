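reactants:
- name: atom_A
  mass_amu: 1.008
  geometry: atom
  sigma: 1.0
  frequencies_cm1: []
  electronic_energy: 0.0
  energy_units: J/mol
  degeneracy: 2.0
  molar_volume_cm3: 15.0
- name: diatom_BC
  mass_amu: 28.0
  geometry: linear
  rotational_constants_cm1: 1.9313
  sigma: 1.0
  frequencies_cm1: 2143.0
  electronic_energy: 0.0
  energy_units: J/mol
  degeneracy: 1.0
  molar_volume_cm3: 35.0
ts:
  name: ts_ABC
  mass_amu: 29.008
  geometry: linear
  rotational_constants_cm1: 1.2
  sigma: 1.0
  frequencies_cm1:
  - 800.0
  - 800.0
  - 2000.0
  electronic_energy: 16736.0
  energy_units: J/mol
  degeneracy: 1.0
  molar_volume_cm3: 45.0
products:
- name: diatom_AB
  mass_amu: 2.016
  geometry: linear
  rotational_constants_cm1: 30.0
  sigma: 1.0
  frequencies_cm1: 3500.0
  electronic_energy: -25104.0
  energy_units: J/mol
  degeneracy: 1.0
- name: atom_C
  mass_amu: 26.992
  geometry: atom
  sigma: 1.0
  frequencies_cm1: []
  electronic_energy: 0.0
  energy_units: J/mol
  degeneracy: 1.0
nu_imag_cm1: 1400.0
dH_cal_mol: -6000.0
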
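{
  "schema": "patchyllps-parameters/1",
  "type": "protein_model",
  "comment": "Hen egg-white lysozyme patchy-sphere geometry; sigma from the solvent-excluded surface volume of the crystal structure, 10 equivalent surface sites.",
  "sigma": 3.43,
  "omega": 0.18,
  "n_sites": 10,
  "molar_mass": 14300,
  "site_distance": 1.715
}
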
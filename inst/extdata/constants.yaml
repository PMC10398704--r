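# Interaction constants for the water-cluster / carbon-nanotube system.
# version 1: UFF-derived Lennard-Jones parameters; epsilon in kcal/mol,
# sigma and lengths in angstrom, densities in atoms/A^2.
version: 1
pairs:
  CH: {epsilon: 0.06797, sigma: 3.3685}
  CO: {epsilon: 0.07937, sigma: 3.6755}
densities:
  eta_c: 0.3812           # graphene-sheet atomic surface density
water:
  sphere_radius: 0.9584   # O-H bond length; radius of the one-molecule sphere
  atoms_per_molecule: 3
  density_g_cm3: 1
tube:
  b1: 13.56               # (20,20) carbon nanotube radius
  L: 500
friction:
  lambda0: 2600           # N s/m^3 at the reference state
  eps_ref: 0.040          # kcal/mol
  b2_ref: 10.40           # A
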
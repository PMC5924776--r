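# Example study configuration: rat-scale idealized left ventricle.
# Units: kPa (organ stress), nm (sarcomere lengths), mm (mesh), s, mL, nM.
seed: 1
active:
  a_on: 0.019        # s^-1 nM^-1
  a_off: 211         # s^-1
  Ck_pos: 1544       # s^-1 nm^-1
  Ck_neg: 264
  kd_pos: 293        # s^-1
  kd_neg: 195
  kdb_pos: 26        # s^-1 nm^-4
  kdb_neg: 47
  k_plus: 54         # s^-1
  k_minus: 12        # s^-1
passive:
  C: 0.262           # kPa
  b_f: 18.48
  b_t: 3.58
  b_fs: 1.627
  kappa: 1000        # kPa
mesh:
  n_trans: 3
  n_circ: 8
  n_long: 6
  r_endo: 3.2        # mm
  z_endo: 6.4        # mm
  wall: 2.0          # mm
drive:
  period: 0.17       # s
  ef: 0.6
calcium:
  period: 0.17
  peak: 1000         # nM
  baseline: 100
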
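# Cluster-profile run: constant molar volume study conditions.
# Desk-scale analogues of this run are exercised by the test suite.
composition: T2O
ensemble: NVT
T: 240
n_molecules: 512
n_b: 32
dt: 2.5e-4        # ps (0.25 fs)
v: 18.0           # cm^3/mol
gamma0: 0.1       # ps^-1 PILE centroid friction
n_equil: 4000000  # 1 ns
n_steps: 40000000 # 10 ns
stride_est: 40
stride_frame: 400
stride_vel: 8
seed: 1
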
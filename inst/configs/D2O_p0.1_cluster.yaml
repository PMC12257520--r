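# Cluster-profile run: constant pressure study conditions (0.1 MPa).
composition: D2O
ensemble: NPT
T: 280
P: 0.1            # MPa
n_molecules: 512
n_b: 32
dt: 2.5e-4
gamma0: 0.1
n_equil: 4000000
n_steps: 40000000
stride_est: 40
stride_frame: 400
stride_vel: 8
seed: 1
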
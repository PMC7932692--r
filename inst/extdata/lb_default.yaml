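# LB-default preset for the sisters-machine lineage generator (version 1).
#
# Structural parameters reflect the emulated growth conditions: 3-min imaging
# cadence, mean generation time ~34 min, and per-generation retentions of the
# heritable growth/adder factors chosen by the closed form
# half_life = ln 2 / (2 ln(1/phi)), targeting sister-pair memory half-lives
# of 4.5 (cycle time) and 3.5 (size) generations. alpha_bar sits slightly
# below ln 2 / 34 because frame-quantized division detection and rate
# fluctuations lengthen the realized mean cycle; it was calibrated against
# the measured ensemble mean.
#
# Noise amplitudes were calibrated by simulation (see run_calibrate and the
# methods vignette) so that generated ensembles reproduce the memory
# statistics the analysis measures: cycle-time CV ~0.2-0.3, sister
# delta-alpha variance ~50% above the neighbor/random plateau at separation
# with its minimum within ~30 min, and fluorescence-difference saturation
# within ~2 generations.
dt_min: 3.0
alpha_bar: 0.0189
delta_bar: 2.0
sigma_delta_rel: 0.06
sigma_r: 0.05
phi_T: 0.925875
sigma_hT: 0.21
phi_L: 0.905724
sigma_hL: 0.20
kappa: 3.5
tau_c: 10.0
sigma_xi: 0.08
tau_xi: 5.0
sigma_env_static: 0.035
sigma_env_dyn: 0.035
tau_env: 34.0
f_bar: 100.0
sigma_f_intr: 10.0
tau_f: 34.0
beta_f: 0.3
sigma_meas_L: 0.01
sigma_meas_f: 0.02
n_traps: 400
n_generations: 26
burnin_generations: 10
seed: 1
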
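# Reference parameter configuration for the polarcpm simulator.
# Units: lengths um, time s, concentrations uM, barbed ends per um^2 (free)
# or per um of edge (pushing), energies in pushing-ends-per-um equivalents.
# Baseline GTPase input rates and three phosphoinositide rates are not
# listed: they are solved from the basal concentrations at load time so the
# resting state is an exact steady state. Override any entry here or via
# default_params(); unknown keys are rejected.
tot_cdc42: 2.4
tot_rac: 7.5
tot_rho: 3.1
bas_cdc42: 1.0
bas_rac: 3.0
bas_rho: 1.25
a_rho: 0.9615385
a_cdc: 1.1111111
n_gtp: 3.0
alpha_rac: 0.5
beta_rho: 0.5
d_gtp: 1.0
D_act: 0.2
D_cyt: 20.0
frac_membrane: 0.25
eta: 0.5
fb_hill: 4.0
fb_half_rel: 1.45
fb_amp_weight: 0.5
bas_pip: 5.0
bas_pip2: 5.0
bas_pip3: 0.25
d_pi: 0.15
k_pip2_pip: 0.02
k_pi3k: 0.005
D_pi: 1.0
rac_2x: 3.0
rho_2x: 1.25
k_arp_act: 0.1
k_arp_cdc42: 0.4
n_arp: 4.0
P2_arp: 9.0
d_arp: 0.2
D_arp: 3.0
k_nuc: 350.0
K_nuc: 100.0
sc_FtoC: 1.0
sc_CtoB: 1.0
v_poly: 0.5
d_F: 0.1
k_cap: 2.8
cap_red_max: 0.9
cap_le_fact: 0.05
le_pip2_rel: 1.15
P2_cap: 9.0
n_cap: 4.0
J_coupling: 4.0
lam_area: 0.02
target_area: 314.16
lam_perim: 0.02
target_perim: 62.83
target_perim_pairs: .na
H_yield: 274.6
temp_T: 108.9
lam_contract: 300.0
rho_thresh: 1.6
nbr_order: 2.0
w_force: 1.0
phi_mem: 30.0
dx: 0.125
dx_ref: 0.125
dt: 0.05
dt_scale_with_dx: yes
renorm_guard: 0.001
edge_scheme: copy
arp_volumetric: yes
min_front_frac: 0.01
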
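# Published refinement-ladder characteristics of the patient-specific
# stenosed-carotid meshes: cell counts, average cell lengths, inlet areas,
# space/cycle-averaged velocity u_mean, normalized quantity of interest f,
# and core counts used for workload accounting. f and area are reported for
# the three finest meshes only.
label,cells,dx,u_mean,area,f,cores
200K,174370,9.13e-4,NA,NA,NA,16
2M,1.84e6,4.63e-4,NA,NA,NA,16
6M,5.97e6,3.04e-4,2.2265e-1,1.8289e-4,4.1426e-4,32
22M,22.43e6,1.92e-4,2.3295e-1,1.7165e-4,3.9989e-4,96
50M,51.14e6,1.44e-4,2.3636e-1,1.6691e-4,3.9453e-4,128
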
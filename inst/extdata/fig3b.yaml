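# Polarity-fraction experiment: 28 synthetic pseudopodium scenes whose
# generator composition encodes the reported mixed actin polarity
# (74% tip-ward / 26% cell-ward among resolved filaments).
n_scenes: 28
n_filaments: 20
tip_fraction: 0.74
noise_sigma: 0.3
pixel_size: 1.1
tilt_range: 60
k: 20
spacing: 8
slab_thickness: 11
box_edge: 32
alpha: 0.05
alpha_stringent: 0.01
n_min: 5
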
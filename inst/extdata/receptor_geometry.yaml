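# Receptor recovery experiment: membrane-only scenes decorated with
# 12-nm-tall bent receptors attached 50-70 nm above the support.
n_scenes: 5
n_filaments: 0
receptor_count: 50
receptor_height: 12
receptor_band: [50, 70]
noise_sigma: 0.3
pixel_size: 1.1
tilt_range: 60
attach_band: [2, 12]
tilt_max: 20
min_sep: 8
k3d: 2
receptor_box: 32
center_offset: 6
height_level: 0.5
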
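# Analysis defaults (all values also embedded in default_config())
sr_analysis: 256      # Hz
trim_s: 0.5           # seconds trimmed per epoch edge
highpass_hz: 0.5
nw: 4                 # multitaper time-bandwidth product
nfft: 1024            # FFT length = window length (4 s at 256 Hz)
k_density_grid: [0.4, 0.6, 0.8]
fdr_q_global: 0.05
fdr_q_local: 0.1
methods: [PLV, PLI]
analysis_band: alpha
seed: 1
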
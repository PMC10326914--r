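# Minimal synthetic model: one precursor component whose single channel
# co-deposits the two P4 marker fragments (internal b 3-8 and y5, both
# acetylated), plus an uncorrelated background channel.
grid: {min: 500, max: 540, bin_width: 0.2}
tic_fluctuation: 0.3
noise_sd: 0.01
peak_width: 0.05
components:
  - label: P4
    lambda: 50
    channels:
      - probability: 0.45
        products:
          - {mz: 512.2827, yield: 0.5}
          - {mz: 530.3045, yield: 0.5}
      - probability: 0.45
        products:
          - {mz: 520.0, yield: 0.5}
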
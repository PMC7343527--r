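# Example run configuration: the shipped cortex/basal-ganglia circuit,
# cross-spectral data features between 5 and 45 Hz, two conditions.
analysis: CSD
sources:
  - name: mmc
    source: MMC
  - name: bgt
    source: BGT
Fdcm: [5, 45]
conditions: ["OFF", "ON"]
inversion:
  restarts: 2
  maxit: 64
seed: 1
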
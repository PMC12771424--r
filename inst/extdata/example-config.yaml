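# Example end-to-end run on simulated ground truth.
# Units are embedded in key names: uM, s, h.
seed: 42
o2_air_uM: 262
calibration: basis     # calibration built from the active basis spectra
proteins:
  PhysHb:
    simulate:
      F_H: 0.83
      k_prime_O2_uM_s: 148
      k_O2_off_s: 5.2
      k_prime_CO_uM_s: 0.58
      k_ox_per_h: 0.88
      noise_sd: 0
      stopped_flow:
        o2_uM: 56.2
        co_uM: 1000
  MarchHb:
    simulate:
      F_H: 0.53
      k_prime_O2_uM_s: 102
      k_O2_off_s: 6.9
      k_prime_CO_uM_s: 2.05
      k_ox_per_h: 0.52
      noise_sd: 0
      stopped_flow:
        o2_uM: 56.2
        co_uM: 1000
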
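# Example simulation config for read_cohort_config(): the two-center study
# layout with the default calibrated class medians.
n_patients: 55
poor_fraction: 0.4909
rwir_median_good: 4.81
rwir_median_poor: 0.69
rho: 0.6
center_id: train
seed: 1
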
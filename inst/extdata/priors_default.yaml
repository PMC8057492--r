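# Informative priors from external validation studies, as consumed by
# read_priors(). Scales resolve via the asymptotic sampling distribution
# sqrt(p (1 - p) / n_effective) with n_effective = case_fraction * n_total
# for sensitivities and (1 - case_fraction) * n_total for specificities.
delta1:              # administrative sensitivity
  estimate: 0.629
  n_total: 3362
  statistic: sensitivity
gamma1:              # administrative specificity
  estimate: 0.938
  n_total: 3362
  statistic: specificity
delta2:              # survey sensitivity
  estimate: 0.553
  n_total: 325
  statistic: sensitivity
gamma2:              # survey specificity
  estimate: 0.937
  n_total: 325
  statistic: specificity
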
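ontario_crosstab.csv
  2x2 cross-classification of administrative-derived (measure 1) and
  survey-derived (measure 2) 12-month mood/anxiety diagnoses in the linked
  2012 Ontario sample (n = 4157). Cell convention: a = positive on both,
  b = survey only, c = administrative only, d = neither.

  NOTE: these cells were solved from the published margins (administrative
  prevalence 10.4%, survey prevalence 13.9%, positive-agreement concordance
  19.4%, n = 4157) via crosstab_from_margins(); the published table's exact
  cells were not machine-readable. If you have the published table, replace
  this file with its exact counts.

priors_default.yaml
  The default informative priors expressed as validation summaries
  (administrative sensitivity/specificity validated against chart review,
  n = 3362; survey sensitivity/specificity validated against clinical
  reinterview, n = 325). Equivalent to default_priors().
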
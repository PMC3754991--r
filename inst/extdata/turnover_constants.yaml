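# Tissue-level constants behind the subadult bone turnover model.
#
# All three blocks parameterize published tissue-level bone physiology and were
# calibrated jointly so that the per-year cancellous-bone turnover table they
# imply agrees with tracer- and biomarker-based estimates for growing humans.
# Edit here (not in code) to revise the physiology.
#
# skeletal_mineral_mass: bone mineral mass M(x) at integer ages 0..20 years,
#   expressed on the skeletal-calcium scale (g). Anchored to standard reference
#   values for the growing skeleton (Mitchell-type body-composition series as
#   tabulated in Leggett's calcium biokinetics model: 28.2 g at birth, ~100 g at
#   1 y, ~219 g at 5 y, ~396 g at 10 y, ~806 g at 15 y). Only year-to-year
#   ratios enter the turnover formula, so the absolute scale is conventional.
skeletal_mineral_mass:
  ages: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
         11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
  mass: [28.2, 100.0001, 141.5253, 168.2575, 199.619, 218.9996, 236.3085,
         260.4898, 294.0901, 338.9, 395.9998, 465.07, 543.0046, 628.1738,
         717.0455, 805.9988, 894.5751, 982.4066, 1061.1509, 1120.6296,
         1149.998]
# remodeling_rate: cancellous-bone remodeling (replacement) rate R(x) at
#   integer ages, as a fraction of existing bone replaced per year. Leggett-type
#   age dependence for trabecular bone: very high in infancy (>300 %/yr),
#   declining smoothly toward the adult cancellous rate by age 20.
remodeling_rate:
  ages: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
         11, 12, 13, 14, 15, 16, 17, 18, 19, 20]
  rate: [3.427372, 0.91357, 0.828121, 0.671263, 0.618004, 0.56897, 0.507003,
         0.451785, 0.402581, 0.358735, 0.319665, 0.288284, 0.259983, 0.23446,
         0.211443, 0.190686, 0.16329, 0.13983, 0.11974, 0.102537, 0.087805]
# mineralization: Ruffoni-type mineralization law for newly formed collagen
#   matrix. `increments[l+1]` is the fraction of a collagen cohort's full
#   mineral load acquired during the l-th year after matrix formation; the
#   first entry (0.826) is fast primary mineralization (~70% within days)
#   plus first-year secondary mineralization. Beyond lag 9 the remaining
#   mass (1 - sum(increments) = 0.086) follows a geometric tail
#   tail_start * tail_ratio^(l-10), so the cumulative law tends to 1.
mineralization:
  increments: [0.825645, 0.022824, 0.017201, 0.01406, 0.012188, 0.008255,
               0.006845, 0.003908, 0.002198, 0.000831]
  tail_start: 0.0012
  tail_ratio: 0.98605381
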
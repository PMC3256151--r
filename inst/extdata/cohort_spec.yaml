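# Default synthetic case-control cohort specification.
#
# Factor-level distributions (percent of population mean) transcribe the
# published plasma-composition table of the LETS case-control population:
# per factor, mean (SD) and observed range, for 473 healthy controls and
# 426 individuals with a prior deep vein thrombosis. Sampling is
# truncated-normal at the printed range.
group_sizes:
  control: 473
  case: 426
factors:
  control:
    fII:   {mean: 104, sd: 15, min: 63,  max: 153}
    fV:    {mean: 131, sd: 33, min: 47,  max: 302}
    fVII:  {mean: 110, sd: 22, min: 41,  max: 171}
    fVIII: {mean: 122, sd: 33, min: 49,  max: 232}
    fIX:   {mean: 103, sd: 21, min: 52,  max: 188}
    fX:    {mean: 103, sd: 17, min: 49,  max: 163}
    AT:    {mean: 99,  sd: 10, min: 63,  max: 125}
    TFPI:  {mean: 92,  sd: 21, min: 46,  max: 171}
  case:
    fII:   {mean: 108, sd: 17, min: 67,  max: 178}
    fV:    {mean: 133, sd: 35, min: 41,  max: 305}
    fVII:  {mean: 114, sd: 25, min: 53,  max: 200}
    fVIII: {mean: 141, sd: 35, min: 53,  max: 318}
    fIX:   {mean: 109, sd: 26, min: 63,  max: 209}
    fX:    {mean: 107, sd: 20, min: 58,  max: 174}
    AT:    {mean: 99,  sd: 11, min: 67,  max: 143}
    TFPI:  {mean: 94,  sd: 21, min: 35,  max: 159}
# Demographic marginals (defaults chosen to match the published subgroup
# counts: 272/473 control women, 254/426 case women; OC use among
# premenopausal women 47/137 (controls) and 30/70 (cases); age split at 45 y
# and BMI split at 26 kg/m2 roughly balanced).
demographics:
  control:
    p_female: 0.575
    age:  {mean: 45, sd: 14, min: 15, max: 72}
    bmi:  {mean: 25.5, sd: 4, min: 17, max: 45}
    p_oc_given_premenopausal_female: 0.34
  case:
    p_female: 0.596
    age:  {mean: 45, sd: 14, min: 15, max: 72}
    bmi:  {mean: 26, sd: 4, min: 17, max: 45}
    p_oc_given_premenopausal_female: 0.43
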
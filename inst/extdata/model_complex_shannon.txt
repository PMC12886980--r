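# Complex structural model. Beyond the simple topology:
#   hemoglobin -> haz      anemia acts on linear growth
#   bcaa -> haz            branched-chain amino acids support growth
#   bcaa -> microbiome     higher BCAA levels track lower diversity
#   aat, age, birth_size   direct covariates of neurodevelopment
# No direct bcaa -> neuro or hemoglobin -> neuro edge: their effects
# are modelled as mediated through the pathophysiology of stunting.

measurement:
  neuro =~ comm + ps + pes + fm + gm
  ses =~ ses_score_cat + mother_edu + mother_age_first_preg + treated_water + rooms
  bcaa =~ alanine + citrulline + valine + leucine + isoleucine
structural:
  neuro ~ ses + haz + shannon + aat + age + birth_size
  haz ~ ses + hemoglobin + bcaa + shannon
  shannon ~ ses + bcaa
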
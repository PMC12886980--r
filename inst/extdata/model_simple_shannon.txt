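# Simple structural model: adds the mediated routes SES -> HAZ,
# SES -> microbiome and microbiome -> HAZ, so the indirect effects of
# SES (through growth and through the microbiome) and of the
# microbiome (through growth) on neurodevelopment are estimable.

measurement:
  neuro =~ comm + ps + pes + fm + gm
  ses =~ ses_score_cat + mother_edu + mother_age_first_preg + treated_water + rooms
structural:
  neuro ~ ses + haz + shannon
  haz ~ ses + shannon
  shannon ~ ses
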
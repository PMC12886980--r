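# Simplest structural model: direct effects only.
# SES (latent), HAZ and the microbiome node each point at the
# neurodevelopment latent; the three sources covary freely (default
# convention for exogenous variables).

measurement:
  neuro =~ comm + ps + pes + fm + gm
  ses =~ ses_score_cat + mother_edu + mother_age_first_preg + treated_water + rooms
structural:
  neuro ~ ses + haz + shannon
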
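# Complex path model: observed variables only. Latents replaced by
# proxies -- rooms + maternal age at first pregnancy for SES, leucine
# for BCAA, the overall (summed) score for the neurodevelopment
# latent.

structural:
  overall_score ~ rooms + mother_age_first_preg + haz + shannon + aat + age + birth_size
  haz ~ hemoglobin + leucine + rooms + mother_age_first_preg + shannon
  shannon ~ leucine + rooms + mother_age_first_preg
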
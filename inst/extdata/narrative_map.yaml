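risk_labels:
  high: "High Risk"
  low: "Low Risk"
patterns:
  - pattern: "GLZLM_SZE\\.PET"
    text: "PET small-zone emphasis ({feature} = {value}) quantifies fragmented
      metabolic architecture, a pattern associated with rapid proliferation
      and hypoxia; in this patient it {direction} the predicted risk
      ({attribution})."
  - pattern: "GLZLM_LGZE\\.CT|GLZLM_LZLGE\\.CT"
    text: "CT large-zone low grey-level texture ({feature} = {value}) captures
      coarse low-density tissue organization linked to invasiveness; here it
      {direction} the predicted risk ({attribution})."
  - pattern: "CONVENTIONAL_HU(max|Q3)"
    text: "Tumor density ({feature} = {value}) summarizes the distribution of
      high-attenuation tissue, a correlate of solid-component burden; it
      {direction} the predicted risk ({attribution})."
  - pattern: "SHAPE_Sphericity"
    text: "Tumor sphericity ({feature} = {value}) reflects 3D morphological
      regularity, with rounder lesions generally less infiltrative; it
      {direction} the predicted risk ({attribution})."
  - pattern: "^[Aa]ge"
    text: "Patient age ({value} years) acts as a non-linear clinical modulator
      of metastatic risk in this model; here it {direction} the predicted
      risk ({attribution})."
  - pattern: "CEA"
    text: "Carcinoembryonic antigen ({feature} = {value}) is a serological
      marker of tumor burden; it {direction} the predicted risk
      ({attribution})."
  - pattern: "SCC_Ag"
    text: "Squamous cell carcinoma antigen ({feature} = {value}) is a
      serological marker associated with squamous histology and disease
      extent; it {direction} the predicted risk ({attribution})."
  - pattern: "_ismissing"
    text: "The recording indicator {feature} flags that the underlying value
      was not documented; its contribution ({attribution}) reflects the
      acquisition pattern rather than patient biology and warrants caution."
fallback: "{feature} = {value} {direction} the predicted risk
  ({attribution})."
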
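{
  "version": "1.0",
  "volume_dependency_exempt": {
    "note": "Features with a known or intrinsic correlation with volume that are nonetheless retained because of their established clinical value and common usage; applied when reducing simulated (or locally measured) screens.",
    "features": [
      {"name": "Volume", "reason": "volume itself; trivially volume-dependent, clinically essential"},
      {"name": "Surface_Area", "reason": "scales with volume by construction; shape descriptor of clinical interest (irregular lesions)"},
      {"name": "Sphericity", "reason": "shape feature; residual rasterisation-driven volume dependence, clinically used"},
      {"name": "Compacity", "reason": "shape feature combining volume and surface area"},
      {"name": "TLSRE", "reason": "SUVmean x volume composite, constructed to be volume-dependent; predictive value in patients"},
      {"name": "Discretised_TLSRE", "reason": "discretised counterpart of the TLSRE composite"},
      {"name": "SUVmin", "reason": "basic SUV statistic in common clinical usage"},
      {"name": "SUVmean", "reason": "basic SUV statistic in common clinical usage"},
      {"name": "SUVstd", "reason": "basic SUV statistic in common clinical usage"},
      {"name": "SUVmax", "reason": "basic SUV statistic in common clinical usage"},
      {"name": "SUVpeak_0.5ml", "reason": "peak SUV; partial-volume-driven volume dependence, clinically used"},
      {"name": "SUVpeak_1.0ml", "reason": "peak SUV; partial-volume-driven volume dependence, clinically used"}
    ]
  },
  "table_replay": {
    "note": "Exceptions required to reproduce the published retained lists exactly from the published exclusion tables: features listed as CoV failures for 177Lu yet present in the final 177Lu retained list. Kept on the published judgement of clinical value; reported by the consistency check.",
    "tc99m": [],
    "lu177": [
      {"name": "SUVmin", "reason": "listed as CoV > 10% in 2 inserts yet retained in the final list"},
      {"name": "NGLDM_Contrast", "reason": "listed as CoV > 10% in 2 inserts yet retained in the final list"},
      {"name": "GLZLM_ZP", "reason": "listed as CoV > 10% in 2 inserts yet retained in the final list"}
    ]
  }
}
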
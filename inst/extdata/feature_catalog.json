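{
  "version": "1.0",
  "note": "67-feature textural-analysis catalogue (LIFEx v6.3-style naming, IBSI-aligned formulas). Assembled by reconciling the published exclusion and retention tables; the reconciliation drops 'Discretised SUVmax', which appears only as an exclusion-table name and whose inclusion would make the catalogue 68 names against the stated 67.",
  "features": [
    {"name": "SUVmin", "display": "SUVmin", "family": "conventional"},
    {"name": "SUVmean", "display": "SUVmean", "family": "conventional"},
    {"name": "SUVstd", "display": "SUVstd", "family": "conventional"},
    {"name": "SUVmax", "display": "SUVmax", "family": "conventional"},
    {"name": "SUVQ1", "display": "SUVQ1", "family": "conventional"},
    {"name": "SUVQ2", "display": "SUVQ2", "family": "conventional"},
    {"name": "SUVQ3", "display": "SUVQ3", "family": "conventional"},
    {"name": "SUV_Skewness", "display": "SUV Skewness", "family": "conventional"},
    {"name": "SUV_Kurtosis", "display": "SUV Kurtosis", "family": "conventional"},
    {"name": "SUV_ExcessKurtosis", "display": "SUV Excess Kurtosis", "family": "conventional"},
    {"name": "SUVpeak_0.5ml", "display": "SUVpeak 0.5 ml", "family": "conventional"},
    {"name": "SUVpeak_1.0ml", "display": "SUVpeak 1.0 ml", "family": "conventional"},
    {"name": "TLSRE", "display": "TLSRE", "family": "conventional"},
    {"name": "Discretised_SUVmin", "display": "Discretised SUVmin", "family": "discretised"},
    {"name": "Discretised_SUVmean", "display": "Discretised SUVmean", "family": "discretised"},
    {"name": "Discretised_SUVstd", "display": "Discretised SUVstd", "family": "discretised"},
    {"name": "Discretised_SUVQ1", "display": "Discretised SUVQ1", "family": "discretised"},
    {"name": "Discretised_SUVQ2", "display": "Discretised SUVQ2", "family": "discretised"},
    {"name": "Discretised_SUVQ3", "display": "Discretised SUVQ3", "family": "discretised"},
    {"name": "Discretised_SUV_Skewness", "display": "Discretised SUV Skewness", "family": "discretised"},
    {"name": "Discretised_SUV_Kurtosis", "display": "Discretised SUV Kurtosis", "family": "discretised"},
    {"name": "Discretised_SUV_ExcessKurtosis", "display": "Discretised SUV Excess Kurtosis", "family": "discretised"},
    {"name": "Discretised_SUVpeak_0.5ml", "display": "Discretised SUVpeak 0.5 ml", "family": "discretised"},
    {"name": "Discretised_SUVpeak_1.0ml", "display": "Discretised SUVpeak 1.0 ml", "family": "discretised"},
    {"name": "Discretised_TLSRE", "display": "Discretised TLSRE", "family": "discretised"},
    {"name": "Histogram_Skewness", "display": "Discretised histogram skewness", "family": "histogram"},
    {"name": "Histogram_Kurtosis", "display": "Discretised histogram kurtosis", "family": "histogram"},
    {"name": "Histogram_ExcessKurtosis", "display": "Discretised histogram excess kurtosis", "family": "histogram"},
    {"name": "Histogram_Entropy_log10", "display": "Discretised histogram entropy log10", "family": "histogram"},
    {"name": "Histogram_Entropy_log2", "display": "Discretised histogram entropy log2", "family": "histogram"},
    {"name": "Histogram_Energy", "display": "Discretised histogram energy", "family": "histogram"},
    {"name": "Volume", "display": "Volume", "family": "shape"},
    {"name": "Sphericity", "display": "Sphericity", "family": "shape"},
    {"name": "Surface_Area", "display": "Surface area", "family": "shape"},
    {"name": "Compacity", "display": "Compacity", "family": "shape"},
    {"name": "GLCM_Homogeneity", "display": "GLCM homogeneity", "family": "glcm"},
    {"name": "GLCM_Energy", "display": "GLCM energy", "family": "glcm"},
    {"name": "GLCM_Contrast", "display": "GLCM contrast", "family": "glcm"},
    {"name": "GLCM_Correlation", "display": "GLCM correlation", "family": "glcm"},
    {"name": "GLCM_Entropy_log10", "display": "GLCM entropy log10", "family": "glcm"},
    {"name": "GLCM_Entropy_log2", "display": "GLCM entropy log2", "family": "glcm"},
    {"name": "GLCM_Dissimilarity", "display": "GLCM dissimilarity", "family": "glcm"},
    {"name": "GLRLM_SRE", "display": "GLRLM SRE", "family": "glrlm"},
    {"name": "GLRLM_LRE", "display": "GLRLM LRE", "family": "glrlm"},
    {"name": "GLRLM_LGRE", "display": "GLRLM LGRE", "family": "glrlm"},
    {"name": "GLRLM_HGRE", "display": "GLRLM HGRE", "family": "glrlm"},
    {"name": "GLRLM_SRLGE", "display": "GLRLM SRLGE", "family": "glrlm"},
    {"name": "GLRLM_SRHGE", "display": "GLRLM SRHGE", "family": "glrlm"},
    {"name": "GLRLM_LRLGE", "display": "GLRLM LRLGE", "family": "glrlm"},
    {"name": "GLRLM_LRHGE", "display": "GLRLM LRHGE", "family": "glrlm"},
    {"name": "GLRLM_GLNU", "display": "GLRLM GLNU", "family": "glrlm"},
    {"name": "GLRLM_RLNU", "display": "GLRLM RLNU", "family": "glrlm"},
    {"name": "GLRLM_RP", "display": "GLRLM RP", "family": "glrlm"},
    {"name": "NGLDM_Coarseness", "display": "NGLDM Coarseness", "family": "ngldm"},
    {"name": "NGLDM_Contrast", "display": "NGLDM Contrast", "family": "ngldm"},
    {"name": "NGLDM_Busyness", "display": "NGLDM Busyness", "family": "ngldm"},
    {"name": "GLZLM_SZE", "display": "GLZLM SZE", "family": "glzlm"},
    {"name": "GLZLM_LZE", "display": "GLZLM LZE", "family": "glzlm"},
    {"name": "GLZLM_LGZE", "display": "GLZLM LGZE", "family": "glzlm"},
    {"name": "GLZLM_HGZE", "display": "GLZLM HGZE", "family": "glzlm"},
    {"name": "GLZLM_SZLGE", "display": "GLZLM SZLGE", "family": "glzlm"},
    {"name": "GLZLM_SZHGE", "display": "GLZLM SZHGE", "family": "glzlm"},
    {"name": "GLZLM_LZLGE", "display": "GLZLM LZLGE", "family": "glzlm"},
    {"name": "GLZLM_LZHGE", "display": "GLZLM LZHGE", "family": "glzlm"},
    {"name": "GLZLM_GLNU", "display": "GLZLM GLNU", "family": "glzlm"},
    {"name": "GLZLM_ZLNU", "display": "GLZLM ZLNU", "family": "glzlm"},
    {"name": "GLZLM_ZP", "display": "GLZLM ZP", "family": "glzlm"}
  ]
}
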
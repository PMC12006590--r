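radionuclide,feature
tc99m,SUVmin
tc99m,SUVmean
tc99m,SUVstd
tc99m,SUVmax
tc99m,SUV Skewness
tc99m,SUV Kurtosis
tc99m,SUVpeak 0.5 ml
tc99m,SUVpeak 1.0 ml
tc99m,TLSRE
tc99m,Discretised SUVmin
tc99m,Discretised SUVstd
tc99m,Discretised SUVQ1
tc99m,Discretised SUVQ2
tc99m,Discretised SUVQ3
tc99m,Discretised SUV skewness
tc99m,Discretised SUV kurtosis
tc99m,Discretised SUVpeak 0.5 ml
tc99m,Discretised SUVpeak 1.0 ml
tc99m,Discretised histogram energy
tc99m,Discretised histogram skewness
tc99m,Discretised histogram kurtosis
tc99m,Discretised histogram entropy log10
tc99m,Discretised histogram entropy log2
tc99m,Sphericity
tc99m,Surface area
tc99m,Compacity
tc99m,GLCM energy
tc99m,GLCM correlation
tc99m,GLCM entropy log10
tc99m,GLCM entropy log2
tc99m,GLRLM SRE
tc99m,GLRLM LRE
tc99m,GLRLM SRHGE
tc99m,GLRLM LRLGE
tc99m,GLRLM LRHGE
tc99m,GLRLM RP
tc99m,NGLDM coarseness
tc99m,GLZLM ZP
tc99m,Volume
lu177,SUVmin
lu177,SUVmean
lu177,SUVstd
lu177,SUVmax
lu177,SUVQ1
lu177,SUVQ2
lu177,SUVQ3
lu177,SUVpeak 0.5 ml
lu177,SUVpeak 1.0 ml
lu177,TLSRE
lu177,Discretised SUVmean
lu177,Discretised SUVstd
lu177,Discretised SUVQ1
lu177,Discretised SUVQ2
lu177,Discretised histogram skewness
lu177,Discretised histogram entropy log10
lu177,Discretised histogram entropy log2
lu177,Discretised histogram energy
lu177,Sphericity
lu177,Surface area
lu177,GLCM homogeneity
lu177,GLCM correlation
lu177,GLCM entropy log10
lu177,GLCM entropy log2
lu177,GLCM dissimilarity
lu177,GLRLM SRE
lu177,GLRLM SRHGE
lu177,GLRLM LRHGE
lu177,GLRLM RP
lu177,NGLDM coarseness
lu177,NGLDM contrast
lu177,GLZLM ZP
lu177,Volume
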
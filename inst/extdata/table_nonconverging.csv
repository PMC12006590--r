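radionuclide,feature
tc99m,SUVQ1
tc99m,SUVQ2
tc99m,SUVQ3
tc99m,Discretised SUVmean
tc99m,Discretised SUVmax
tc99m,Discretised TLSRE
tc99m,GLCM homogeneity
tc99m,GLCM contrast
tc99m,GLCM dissimilarity
tc99m,GLRLM LGRE
tc99m,GLRLM HGRE
tc99m,GLRLM SRLGE
tc99m,GLRLM GLNU
tc99m,GLRLM RLNU
tc99m,NGLDM Contrast
tc99m,NGLDM Busyness
tc99m,GLZLM SZE
tc99m,GLZLM LZE
tc99m,GLZLM LGZE
tc99m,GLZLM HGZE
tc99m,GLZLM SZLGE
tc99m,GLZLM SZHGE
tc99m,GLZLM LZLGE
tc99m,GLZLM LZHGE
tc99m,GLZLM GLNU
tc99m,GLZLM ZLNU
lu177,SUV Skewness
lu177,SUV Kurtosis
lu177,SUV Excess Kurtosis
lu177,Discretised SUVmin
lu177,Discretised SUVmax
lu177,Discretised SUVQ3
lu177,Discretised Skewness
lu177,Discretised SUVpeak 0.5 ml
lu177,Discretised SUVpeak 1 ml
lu177,Discretised TLSRE
lu177,GLRLM HGRE
lu177,GLRLM GLNU
lu177,GLRLM RLNU
lu177,NGLDM Busyness
lu177,GLZLM SZE
lu177,GLZLM LZE
lu177,GLZLM LGZE
lu177,GLZLM HGZE
lu177,GLZLM SZLGE
lu177,GLZLM SZHGE
lu177,GLZLM LZLGE
lu177,GLZLM LZHGE
lu177,GLZLM GLNU
lu177,GLZLM ZLNU
lu177,GLRLM LRE
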
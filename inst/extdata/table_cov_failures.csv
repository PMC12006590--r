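radionuclide,feature,n_inserts
tc99m,Discretised SUV excess Kurtosis,1
tc99m,SUV excess Kurtosis,1
tc99m,Discretised Histogram Excess Kurtosis,2
tc99m,GLZLM LZLGE,2
tc99m,GLZLM LZE,3
tc99m,GLZLM SZHGE,3
tc99m,GLZLM SZLGE,3
tc99m,GLZLM ZLNU,3
tc99m,NGLDM Busyness,3
lu177,Compacity,1
lu177,Discretised SUV Kurtosis,1
lu177,Discretised SUV Skewness,1
lu177,Discretised SUVmin,1
lu177,GLZCM contrast,1
lu177,GLRLM LGRE,1
lu177,GLRLM LRLGE,1
lu177,GLRLM SRLGE,1
lu177,SUV Kurtosis,1
lu177,SUV Skewness,1
lu177,GLZLM SZLGE,1
lu177,GLZLM ZLNU,1
lu177,SUV Excess Kurtosis,1
lu177,Discretised Histogram Kurtosis,2
lu177,GLZLM SZE,2
lu177,GLZLM SZHGE,2
lu177,GLZLM ZP,2
lu177,NGLDM Busyness,2
lu177,NGLDM Contrast,2
lu177,SUVmin,2
lu177,GLZLM LZLGE,2
lu177,Discretised histogram Excess Kurtosis,3
lu177,Discretised SUV excess Kurtosis,3
lu177,GLCM Energy,3
lu177,GLZLM GLNU,3
lu177,GLZLM HGZE,3
lu177,GLZLM LGZE,3
lu177,GLZLM LZE,3
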
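# Descending-aorta ROI summaries for the two packaged urogram cases.
# role: full = full ICM dose at 70 keV VMI; reduced_70 = reduced dose at 70 keV;
# reduced_low = reduced dose at the CNR-matched lower keV (61 / 45 keV).
# reported_cnr is display-only context (psoas background stats not recorded).
patient,role,vmi_kev,mean_hu,sd_hu,reported_cnr
1,full,70,212.1,12.1,9.82
1,reduced_70,70,156.4,15.2,2.89
1,reduced_low,61,211.1,19.1,8.33
2,full,70,215.6,17.4,10.19
2,reduced_70,70,100.1,18.1,3.39
2,reduced_low,45,218.1,37.3,4.82
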
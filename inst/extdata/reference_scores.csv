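subject_id,group,diagnosis,radiomics,cnn
pat01,dementia,FTD,100,99.7
pat02,dementia,DLB,92.3,98.7
pat03,dementia,FTD,98.6,98.7
pat04,dementia,MCI,93.9,91.8
pat05,dementia,FTD,99.5,96.8
pat06,dementia,AD,99.5,98.2
pat07,dementia,FTD,98.4,91.7
pat08,dementia,FTD,99.9,98
pat09,dementia,AD,99.5,94
pat10,dementia,FTD,93.8,88.1
hc01,control,HC,99.6,77.3
hc02,control,HC,97.9,93.5
hc03,control,HC,99.3,86.8
hc04,control,HC,94.1,97
hc05,control,HC,97.6,88.4
hc06,control,HC,100,85
hc07,control,HC,95.5,81.1
hc08,control,HC,96.7,80.9
hc09,control,HC,100,83.7
hc10,control,HC,99.8,84.1
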
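characteristic,level,stroma_low,stroma_high
age_group,<=50,97,52
age_group,>50,56,35
grade,I,27,13
grade,II,92,49
grade,III,34,25
subtype,TNBC,37,26
subtype,HER2-positive,34,27
subtype,Luminal-HER2-negative,82,34
nodal,Positive,77,54
nodal,Negative,76,33
er,Positive,78,28
er,Negative,75,59
her2,Positive,34,27
her2,Negative,119,60
pr,Positive,76,31
pr,Negative,77,56
menopausal,Premenopausal,92,42
menopausal,Postmenopausal,61,45
tumor_size,T1,21,14
tumor_size,T2,111,51
tumor_size,T3,21,22
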
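no	NEGEX
not	NEGEX
absent	NEGEX
negative	NEGEX
denies	NEGEX
without	NEGEX
adequate to rule her out	NEGEX
mother	FAMILY
father	FAMILY
brother	FAMILY
sister	FAMILY
wife	FAMILY
husband	FAMILY
daughter	FAMILY
son	FAMILY
suspicion	RISK
suspicious	RISK
probable	RISK
possible	RISK
likely	RISK
concern	RISK
worrisome	RISK
increase	QUAL
increased	QUAL
invasive	QUAL
diffuse	QUAL
decrease	QUAL
extensive	QUAL
mild	QUAL
moderate	QUAL
severe	QUAL
stable	QUAL
progressive	QUAL
metastasis	METASTASIS
metastases	METASTASIS
metastatic	METASTASIS
lesion	LESION
lesions	LESION
nodule	LESION
tumor	TUMOR
carcinoma	CARCINOMA
adenocarcinoma	CARCINOMA
chemotherapy	CHEMO
chemo	CHEMO
radiation	RADIATION
radiotherapy	RADIATION
biopsy	BIOPSY
scan	IMAGING
imaging	IMAGING
mri	IMAGING
pain	SYMPTOM
fatigue	SYMPTOM
nausea	SYMPTOM
dyspnea	SYMPTOM
hospice	HOSPICE
comfort care	HOSPICE
palliative	PALLIATIVE
deteriorating	DETERIORATION
deterioration	DETERIORATION
decline	DETERIORATION
declining	DETERIORATION
unresponsive	CRITICAL
critical	CRITICAL
dnr	CRITICAL
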
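term	mesh_id
epilepsy	D004827
epileptic seizures	D012640
seizures	D012640
temporal lobe epilepsy	D004833
TLE	D004833
Alzheimer disease	D000544
Alzheimer's disease	D000544
AD	D000544
Parkinson disease	D010300
Parkinson's disease	D010300
PD	D010300
synthetic cortical syndrome	D900001
synthetic hepatic syndrome	D900002
synthetic renal syndrome	D900003
synthetic spinal syndrome	D900004
synthetic gastric syndrome	D900005
synthetic ocular syndrome	D900006
synthetic dermal syndrome	D900007
synthetic cardiac syndrome	D900008
synthetic pulmonary syndrome	D900009
synthetic lingual syndrome	D900010
synthetic tonsillar syndrome	D900011
synthetic parietal syndrome	D900012
synthetic femoral syndrome	D900013
synthetic adrenal syndrome	D900014
synthetic pineal syndrome	D900015
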
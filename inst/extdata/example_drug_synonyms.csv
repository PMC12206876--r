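term,canonical
PARAPLATIN,CARBOPLATIN
CARBOPLATINO,CARBOPLATIN
CARBOPLATIN INJECTION,CARBOPLATIN
CBDCA,CARBOPLATIN
TAXOL,PACLITAXEL
ABRAXANE,PACLITAXEL
ALIMTA,PEMETREXED
GEMZAR,GEMCITABINE
KEYTRUDA,PEMBROLIZUMAB
TECENTRIQ,ATEZOLIZUMAB
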
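pt,soc
ANAEMIA,Blood and lymphatic system disorders
LEUKOPENIA,Blood and lymphatic system disorders
THROMBOCYTOPENIA,Blood and lymphatic system disorders
NEUTROPENIA,Blood and lymphatic system disorders
POLYNEUROPATHY,Nervous system disorders
NEUROPATHY PERIPHERAL,Nervous system disorders
NAUSEA,Gastrointestinal disorders
VOMITING,Gastrointestinal disorders
ABDOMINAL PAIN,Gastrointestinal disorders
ACUTE KIDNEY INJURY,Renal and urinary disorders
HYPOTHYROIDISM,Endocrine disorders
SEPSIS,Infections and infestations
NEUTROPENIC SEPSIS,Infections and infestations
FATIGUE,General disorders and administration site conditions
VISION BLURRED,Eye disorders
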
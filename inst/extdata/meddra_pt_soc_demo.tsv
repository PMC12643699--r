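pt	soc
Neutropenia	Blood and lymphatic system disorders
Anaemia	Blood and lymphatic system disorders
Febrile neutropenia	Blood and lymphatic system disorders
Thrombocytopenia	Blood and lymphatic system disorders
Leukopenia	Blood and lymphatic system disorders
Pancytopenia	Blood and lymphatic system disorders
Diarrhoea	Gastrointestinal disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Stomatitis	Gastrointestinal disorders
Neuropathy peripheral	Nervous system disorders
Neurotoxicity	Nervous system disorders
Dysarthria	Nervous system disorders
Loss of consciousness	Nervous system disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Pulmonary embolism	Respiratory, thoracic and mediastinal disorders
Pneumonitis	Respiratory, thoracic and mediastinal disorders
Erythema	Skin and subcutaneous tissue disorders
Hyperhidrosis	Skin and subcutaneous tissue disorders
Flushing	Vascular disorders
Hypotension	Vascular disorders
Sepsis	Infections and infestations
Septic shock	Infections and infestations
Infection	Infections and infestations
Pyrexia	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Death	General disorders and administration site conditions
Dehydration	Metabolism and nutrition disorders
Hypokalaemia	Metabolism and nutrition disorders
Decreased appetite	Metabolism and nutrition disorders
Back pain	Musculoskeletal and connective tissue disorders
Hepatotoxicity	Hepatobiliary disorders
Tachycardia	Cardiac disorders
Chest discomfort	Cardiac disorders
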
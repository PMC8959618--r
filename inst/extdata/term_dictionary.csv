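"raw_term","pt","soc"
"Extrapyramidal disorder","Extrapyramidal disorder","Nervous system disorders"
"Akathisia","Akathisia","Nervous system disorders"
"Constipation","Constipation","Gastrointestinal disorders"
"Drooling","Drooling","Gastrointestinal disorders"
"White blood cell count decreased","White blood cell count decreased","Investigations"
"Tremor","Tremor","Nervous system disorders"
"Somnolence","Somnolence","Nervous system disorders"
"Hepatic function abnormal","Hepatic function abnormal","Hepatobiliary disorders"
"Dizziness","Dizziness","Nervous system disorders"
"Tachycardia","Tachycardia","Cardiac disorders"
"Nausea","Nausea","Gastrointestinal disorders"
"Vomiting","Vomiting","Gastrointestinal disorders"
"Weight increased","Weight increased","Investigations"
"Dystonia","Dystonia","Nervous system disorders"
"Electrocardiogram QT prolonged","Electrocardiogram QT prolonged","Investigations"
"Headache","Headache","Nervous system disorders"
"Palpitations","Palpitations","Cardiac disorders"
"Rash","Rash","Skin and subcutaneous tissue disorders"
"Insomnia","Insomnia","Psychiatric disorders"
"Pyrexia","Pyrexia","General disorders and administration site conditions"
"Fatigue","Fatigue","General disorders and administration site conditions"
"Vision blurred","Vision blurred","Eye disorders"
"Blood glucose increased","Blood glucose increased","Investigations"
"Agitation","Agitation","Psychiatric disorders"
"Anxiety","Anxiety","Psychiatric disorders"
"Dry mouth","Dry mouth","Gastrointestinal disorders"
"Hypertonia","Hypertonia","Nervous system disorders"
"Orthostatic hypotension","Orthostatic hypotension","Vascular disorders"
"Pruritus","Pruritus","Skin and subcutaneous tissue disorders"
"Hypotension","Hypotension","Vascular disorders"
"Muscle rigidity","Muscle rigidity","Musculoskeletal and connective tissue disorders"
"Blood pressure decreased","Blood pressure decreased","Investigations"
"Hyperprolactinaemia","Hyperprolactinaemia","Endocrine disorders"
"Dyspnoea","Dyspnoea","Respiratory, thoracic and mediastinal disorders"
"Abnormal sensation in eye","Abnormal sensation in eye","Eye disorders"
"Sinus bradycardia","Sinus bradycardia","Cardiac disorders"
"Dysphagia","Dysphagia","Gastrointestinal disorders"
"Obesity","Obesity","Metabolism and nutrition disorders"
"Pollakiuria","Pollakiuria","Renal and urinary disorders"
"Urinary incontinence","Urinary incontinence","Renal and urinary disorders"
"Amenorrhoea","Amenorrhoea","Reproductive system and breast disorders"
"Galactorrhoea","Galactorrhoea","Reproductive system and breast disorders"
"Tongue induration","Tongue induration","Gastrointestinal disorders"
"Nuchal rigidity","Nuchal rigidity","Musculoskeletal and connective tissue disorders"
"restlessness","Akathisia","Nervous system disorders"
"BP decreased","Blood pressure decreased","Investigations"
"drooling saliva","Drooling","Gastrointestinal disorders"
"EPS symptoms","Extrapyramidal disorder","Nervous system disorders"
"liver enzymes raised","Hepatic function abnormal","Hepatobiliary disorders"
"low blood pressure standing","Orthostatic hypotension","Vascular disorders"
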
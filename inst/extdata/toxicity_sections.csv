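section
Acute Effects
Antidote and Emergency Treatment
Carcinogen Classification
Carcinogenicity
Drug Interactions
Ecotoxicity Values
Evidence for Carcinogenicity
Exposure Routes
Eye Symptoms
Genotoxicity
Health Effects
Hepatotoxicity
Human Toxicity Excerpts
Human Toxicity Values
Interactions
Medical Surveillance
National Toxicology Program Studies
Nephrotoxicity
Neurotoxicity
NIOSH Toxicity Data
Non-Human Toxicity Excerpts
Non-Human Toxicity Values
Ongoing Test Status
Populations at Special Risk
Protein Binding
Reproductive and Developmental Toxicity
Skin Symptoms
Symptoms
Target Organs
Toxicity Data
Toxicity Summary
TSCA Test Submissions
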
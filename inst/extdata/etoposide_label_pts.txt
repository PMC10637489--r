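# Adverse-event preferred terms documented in public etoposide prescribing
# information (package insert / SmPC); used for novelty flagging.
Thrombocytopenia
Leukopenia
Neutropenia
Febrile neutropenia
Anaemia
Myelosuppression
Nausea
Vomiting
Diarrhoea
Abdominal pain
Stomatitis
Oesophagitis
Mucositis
Alopecia
Rash
Pruritus
Hypotension
Anaphylactic reaction
Hypersensitivity
Hepatotoxicity
Peripheral sensory neuropathy
Neuropathy peripheral
Neurotoxicity
Pneumonitis
Asthenia
Fatigue
Pyrexia
Decreased appetite
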
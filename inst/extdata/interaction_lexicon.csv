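pattern,category,direction,alert
"weaken(ed)?[^.]*target (therapy|treatment)|target therapy[^.]*weaken|resistance to (bortezomib|imatinib|targeted)",Weakened target therapy,antagonistic,FALSE
"genotoxic|DNA damage",Enhanced genotoxicity,synergistic,TRUE
"ionizing radiation|radiothera|radiosensitiz|radiation",Enhanced radiotherapy,synergistic,FALSE
"metastas",Metastasis inhibition,synergistic,FALSE
"(inhibit|suppress|prevent|protect)[^.]*(carcinogen|tumorigen)|(carcinogen|tumorigen)[^.]*(inhibit|suppress)",Carcinogenesis inhibition,synergistic,FALSE
"bioavailab|p-glycoprotein|p-gp|cytochrome p450|cyp3a|cyp2|drug absorption|efflux",Enhanced bioavailability,synergistic,FALSE
"chemothera|cytotoxic|synergi|potentiat[^.]*(cisplatin|docetaxel|doxorubicin|paclitaxel|5-fluorouracil)|sensitiz[^.]*(drug|agent|cisplatin|docetaxel)",Enhanced chemotherapy,synergistic,FALSE
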
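{
  "name": "placeholder-45",
  "version": "1.0",
  "notes": "Synthetic placeholder instrument. The true 45 criterion texts and their weight/domain assignment are not published; this default reproduces the instrument's published shape (45 binary criteria, four domains, weights 1-3) with invented but field-plausible items. Per-domain maxima: prescription 25, gmp 8, safety_of_use 37, laboratory_testing 12; maximum total 82. Replace with a user-supplied rubric for any real evaluation.",
  "criteria": [
    {"id": "p01", "label": "Concentration of each active ingredient (mg/ml or mg/unit) declared", "domain": "prescription", "weight": 3},
    {"id": "p02", "label": "Correspondence between number of drops and mg of main phytocannabinoids", "domain": "prescription", "weight": 3},
    {"id": "p03", "label": "Qualitative phytocannabinoid composition (CBD/THC/minor cannabinoids) declared", "domain": "prescription", "weight": 3},
    {"id": "p04", "label": "Total content per container (volume or unit count) declared", "domain": "prescription", "weight": 3},
    {"id": "p05", "label": "Pharmaceutical form and route of administration stated", "domain": "prescription", "weight": 3},
    {"id": "p06", "label": "Spectrum class (full spectrum, broad spectrum, isolate) stated", "domain": "prescription", "weight": 3},
    {"id": "p07", "label": "Excipients and vehicle listed", "domain": "prescription", "weight": 2},
    {"id": "p08", "label": "Batch/lot number present on label", "domain": "prescription", "weight": 2},
    {"id": "p09", "label": "Expiry date present on label", "domain": "prescription", "weight": 2},
    {"id": "p10", "label": "Physical and organoleptic characteristics of the product described", "domain": "prescription", "weight": 1},
    {"id": "g01", "label": "Manufacturer identity and manufacturing site declared", "domain": "gmp", "weight": 2},
    {"id": "g02", "label": "Good-manufacturing-practice certification referenced", "domain": "gmp", "weight": 2},
    {"id": "g03", "label": "Country of origin of raw material declared", "domain": "gmp", "weight": 1},
    {"id": "g04", "label": "Extraction method described", "domain": "gmp", "weight": 1},
    {"id": "g05", "label": "Quality management or pharmacovigilance contact provided", "domain": "gmp", "weight": 1},
    {"id": "g06", "label": "Traceability statement (batch records, recall mechanism)", "domain": "gmp", "weight": 1},
    {"id": "s01", "label": "Contraindications stated", "domain": "safety_of_use", "weight": 3},
    {"id": "s02", "label": "Precautions and warnings stated", "domain": "safety_of_use", "weight": 3},
    {"id": "s03", "label": "Instructions for use and dose titration guidance provided", "domain": "safety_of_use", "weight": 3},
    {"id": "s04", "label": "Adverse events and side effects listed", "domain": "safety_of_use", "weight": 3},
    {"id": "s05", "label": "Drug interaction information provided", "domain": "safety_of_use", "weight": 3},
    {"id": "s06", "label": "Package leaflet or information leaflet publicly available", "domain": "safety_of_use", "weight": 3},
    {"id": "s07", "label": "Storage conditions and precautions stated", "domain": "safety_of_use", "weight": 2},
    {"id": "s08", "label": "Use in pregnancy and breastfeeding addressed", "domain": "safety_of_use", "weight": 2},
    {"id": "s09", "label": "Paediatric and elderly use addressed", "domain": "safety_of_use", "weight": 2},
    {"id": "s10", "label": "Overdose guidance provided", "domain": "safety_of_use", "weight": 2},
    {"id": "s11", "label": "Warning about driving and operating machinery", "domain": "safety_of_use", "weight": 2},
    {"id": "s12", "label": "Keep-out-of-reach-of-children warning present", "domain": "safety_of_use", "weight": 2},
    {"id": "s13", "label": "Shelf life after opening stated", "domain": "safety_of_use", "weight": 2},
    {"id": "s14", "label": "Prescription-only / medical supervision statement present", "domain": "safety_of_use", "weight": 2},
    {"id": "s15", "label": "Safe disposal instructions provided", "domain": "safety_of_use", "weight": 1},
    {"id": "s16", "label": "Tamper-evidence or seal-integrity notice present", "domain": "safety_of_use", "weight": 1},
    {"id": "s17", "label": "Allergen statement present", "domain": "safety_of_use", "weight": 1},
    {"id": "l01", "label": "Certificate of laboratory analysis (CoA) publicly available", "domain": "laboratory_testing", "weight": 1},
    {"id": "l02", "label": "CoA issued by a third-party laboratory", "domain": "laboratory_testing", "weight": 1},
    {"id": "l03", "label": "CoA matches the batch offered for sale", "domain": "laboratory_testing", "weight": 1},
    {"id": "l04", "label": "Quantified CBD content in CoA", "domain": "laboratory_testing", "weight": 1},
    {"id": "l05", "label": "Quantified THC content in CoA", "domain": "laboratory_testing", "weight": 1},
    {"id": "l06", "label": "Minor phytocannabinoid profile reported", "domain": "laboratory_testing", "weight": 1},
    {"id": "l07", "label": "Terpene characterization reported", "domain": "laboratory_testing", "weight": 1},
    {"id": "l08", "label": "Residual solvents tested", "domain": "laboratory_testing", "weight": 1},
    {"id": "l09", "label": "Heavy metals tested", "domain": "laboratory_testing", "weight": 1},
    {"id": "l10", "label": "Mycotoxins/aflatoxins tested", "domain": "laboratory_testing", "weight": 1},
    {"id": "l11", "label": "Microbiological contamination (CFU) tested", "domain": "laboratory_testing", "weight": 1},
    {"id": "l12", "label": "Pesticide residues tested", "domain": "laboratory_testing", "weight": 1}
  ]
}
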
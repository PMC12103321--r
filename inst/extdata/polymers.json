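{
  "registry_version": "1.0",
  "comment": "Repeat-unit or compound empirical formulas in Hill notation. Densities in g/cm3: PS as used for the centrifugation work; other polymer densities are nominal handbook values for the pristine material. Au doping of in-house PE/PP/PVC particles is ignored in carbon-fraction arithmetic (dopant mass fraction unknown).",
  "materials": [
    {"name": "PS",        "label": "polystyrene",                 "formula": "C8H8",    "density": 1.05},
    {"name": "PE",        "label": "polyethylene",                "formula": "CH2",     "density": 0.95},
    {"name": "PP",        "label": "polypropylene",               "formula": "C3H6",    "density": 0.905},
    {"name": "PVC",       "label": "polyvinyl chloride",          "formula": "C2H3Cl",  "density": 1.41},
    {"name": "PET",       "label": "polyethylene terephthalate",  "formula": "C10H8O4", "density": 1.38},
    {"name": "cellulose", "label": "cellulose (anhydroglucose)",  "formula": "C6H10O5", "density": 1.5},
    {"name": "KHP",       "label": "potassium hydrogen phthalate","formula": "C8H5KO4", "density": 1.636},
    {"name": "Na2CO3",    "label": "sodium carbonate",            "formula": "Na2CO3",  "density": 2.54}
  ]
}
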
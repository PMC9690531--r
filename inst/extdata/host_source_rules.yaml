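# Host-source classification rules.
# Categories are matched in file order (precedence); keywords are lowercase
# substrings tested against both host_species and isolation_source.
rules:
  - category: human
    keywords: [human, homo sapiens, homo_sapiens, patient, clinical,
               hospital, urine, blood, sputum, wound, stool]
  - category: animal
    keywords: [animal, bovine, cattle, cow, calf, pig, swine, porcine,
               sus scrofa, chicken, poultry, gallus, avian, duck, turkey,
               dog, canine, cat, feline, horse, equine, sheep, ovine, goat,
               mouse, murine, rat, rabbit, fish, mussel, shrimp]
  - category: wastewater and sludge
    keywords: [sludge, sewage, wastewater, waste water, effluent, wwtp]
  - category: miscellaneous sources
    keywords: [soil, water, river, lake, sea, sediment, food, milk, plant,
               vegetable, environment, compost, manure]
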
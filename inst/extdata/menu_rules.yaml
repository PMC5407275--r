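# Menu-listing acceptability rules. Only listings the packaged audit itself
# adjudicates are encoded; supply a custom file for anything else.
# "Genus *" is a genus-level wildcard. species_specific marks rules whose
# phrase names one species (these outrank generic phrases when matching).
rules:
  tuna:
    acceptable: ["Thunnus *"]
    species_specific: false
  yellowfin:
    acceptable: ["Thunnus albacares"]
    species_specific: true
  ahi:
    acceptable: ["Thunnus albacares"]
    species_specific: true
  albacore:
    acceptable: ["Thunnus alalunga"]
    species_specific: true
  chilean seabass:
    acceptable: ["Dissostichus eleginoides"]
    species_specific: true
  rock shrimp:
    acceptable: ["Sicyonia brevirostris"]
    species_specific: true
  snapper:
    acceptable: ["Lutjanus *"]
    species_specific: false
  calamari:
    acceptable: ["Uroteuthis edulis", "Loligo *", "Doryteuthis *"]
    species_specific: false
  gulf shrimp:
    acceptable: ["Farfantepenaeus *"]
    species_specific: false
  barramundi:
    acceptable: ["Lates calcarifer"]
    species_specific: true
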
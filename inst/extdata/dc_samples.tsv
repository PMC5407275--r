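# Per-sample method observations for the 12 Washington, D.C. restaurant
# seafood samples: database-identity candidates (taxon:percent pairs within
# the reporting band of the best hit), ML placement with bootstrap/posterior
# node support (posterior printed as integer percent), and the observed
# diagnostic-key profile for tuna samples. NA = method not applicable.
sample_id	restaurant	menu_listing	identity_candidates	phylo_species	phylo_level	phylo_members	phylo_boot	phylo_pp	key_profile
bv_rockshrimp	Bobby Van's Steakhouse	Rock Shrimp Tempura	Litopenaeus vannamei:100	Litopenaeus vannamei	species	Litopenaeus vannamei	88	87	NA
bv_calamari	Bobby Van's Steakhouse	Calamari	Uroteuthis edulis:100	Uroteuthis edulis	species	Uroteuthis edulis	98	100	NA
gb_yellowfin	Gordon Biersch	Yellowfin Tuna	Thunnus albacares:100;Thunnus atlanticus:100;Thunnus obesus:100	Thunnus albacares	species	Thunnus albacares	11	6	CCCCACGTATTGAC
gb_gulfshrimp	Gordon Biersch	Gulf Shrimp	Farfantepenaeus aztecus:99.85	Farfantepenaeus aztecus	species	Farfantepenaeus aztecus	100	100	NA
oc_seabass	The Oceanaire	Chilean Seabass	Dissostichus mawsoni:100	Dissostichus mawsoni	species	Dissostichus mawsoni	99	100	NA
oc_barramundi	The Oceanaire	Australian Barramundi	Lates uwisara:100;Lates calcarifer:100	Lates calcarifer	species	Lates calcarifer	100	99	NA
joes_ahi	Joe's Seafood, Prime Steak and Snow Crab	Ahi Tuna Tartare	Thunnus alalunga:100;Thunnus obesus:99.83;Thunnus orientalis:99.67;Thunnus maccoyii:99.67	NA	genus-or-higher	Thunnus alalunga;Thunnus albacares;Thunnus atlanticus;Thunnus maccoyii;Thunnus obesus;Thunnus orientalis	31	9	CTCCGCATATCAAT
joes_seabass	Joe's Seafood, Prime Steak and Snow Crab	Chilean Seabass	Dissostichus eleginoides:100	Dissostichus eleginoides	species	Dissostichus eleginoides	99	99	NA
ls_snapper	Legal Sea Foods	Snapper Salsa Verde	Lutjanus guttatus:100;Lutjanus sp.:100;Lutjanus synagris:98.31	NA	genus-or-higher	Lutjanus guttatus;Lutjanus synagris	85	41	NA
ls_tuna	Legal Sea Foods	Everything Tuna	Thunnus obesus:100;Thunnus albacares:99.84	Thunnus obesus	species	Thunnus obesus	61	52	CCCTACGGATTGAC
mc_albacore	McCormick and Schmick's	Sesame Crusted Albacore Tuna	Thunnus albacares:100;Thunnus atlanticus:100;Thunnus obesus:100	Thunnus albacares	species	Thunnus albacares	14	6	CCCCACGTATTGAC
mc_seabass	McCormick and Schmick's	Pesto Chilean Seabass	Dissostichus eleginoides:100	Dissostichus eleginoides	species	Dissostichus eleginoides	99	99	NA
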
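# Tested topology hypotheses and stepping-stone marginal log-likelihoods
# for the Washington, D.C. restaurant samples. One row per hypothesis;
# level is the taxonomic rank of the constrained reference group.
sample_id	restaurant	menu_listing	mode	target_taxon	level	marginal_lnL
bv_rockshrimp	Bobby Van's Steakhouse	Rock Shrimp Tempura	monophyletic	Sicyonia	genus	-6984.27
bv_rockshrimp	Bobby Van's Steakhouse	Rock Shrimp Tempura	not_monophyletic	Sicyonia	genus	-6951.31
bv_rockshrimp	Bobby Van's Steakhouse	Rock Shrimp Tempura	monophyletic	Litopenaeus vannamei	species	-6940.03
gb_yellowfin	Gordon Biersch	Yellowfin Tuna	monophyletic	Thunnus albacares	species	-5463.35
gb_yellowfin	Gordon Biersch	Yellowfin Tuna	not_monophyletic	Thunnus albacares	species	-5471.71
oc_seabass	The Oceanaire	Chilean Seabass	monophyletic	Dissostichus eleginoides	species	-5532.76
oc_seabass	The Oceanaire	Chilean Seabass	not_monophyletic	Dissostichus eleginoides	species	-5469.00
oc_seabass	The Oceanaire	Chilean Seabass	monophyletic	Dissostichus mawsoni	species	-5457.31
oc_barramundi	The Oceanaire	Australian Barramundi	monophyletic	Lates calcarifer	species	-5458.50
oc_barramundi	The Oceanaire	Australian Barramundi	not_monophyletic	Lates calcarifer	species	-5472.81
joes_ahi	Joe's Seafood, Prime Steak and Snow Crab	Ahi Tuna Tartare	monophyletic	Thunnus albacares	species	-5485.01
joes_ahi	Joe's Seafood, Prime Steak and Snow Crab	Ahi Tuna Tartare	not_monophyletic	Thunnus albacares	species	-5472.92
joes_ahi	Joe's Seafood, Prime Steak and Snow Crab	Ahi Tuna Tartare	monophyletic	Thunnus alalunga	species	-5460.75
joes_seabass	Joe's Seafood, Prime Steak and Snow Crab	Chilean Seabass	monophyletic	Dissostichus eleginoides	species	-5460.67
joes_seabass	Joe's Seafood, Prime Steak and Snow Crab	Chilean Seabass	not_monophyletic	Dissostichus eleginoides	species	-5470.68
joes_seabass	Joe's Seafood, Prime Steak and Snow Crab	Chilean Seabass	monophyletic	Dissostichus mawsoni	species	-5530.80
ls_snapper	Legal Sea Foods	Snapper Salsa Verde	monophyletic	Lutjanus	genus	-5432.61
ls_snapper	Legal Sea Foods	Snapper Salsa Verde	not_monophyletic	Lutjanus	genus	-5490.42
ls_snapper	Legal Sea Foods	Snapper Salsa Verde	monophyletic	Lutjanus synagris	species	-5460.98
ls_snapper	Legal Sea Foods	Snapper Salsa Verde	monophyletic	Lutjanus guttatus	species	-5460.73
mc_albacore	McCormick and Schmick's	Sesame Crusted Albacore Tuna	monophyletic	Thunnus alalunga	species	-5492.50
mc_albacore	McCormick and Schmick's	Sesame Crusted Albacore Tuna	not_monophyletic	Thunnus alalunga	species	-5471.55
mc_albacore	McCormick and Schmick's	Sesame Crusted Albacore Tuna	monophyletic	Thunnus albacares	species	-5461.95
mc_seabass	McCormick and Schmick's	Pesto Chilean Seabass	monophyletic	Dissostichus eleginoides	species	-5460.35
mc_seabass	McCormick and Schmick's	Pesto Chilean Seabass	not_monophyletic	Dissostichus eleginoides	species	-5531.72
mc_seabass	McCormick and Schmick's	Pesto Chilean Seabass	monophyletic	Dissostichus mawsoni	species	-5469.87
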
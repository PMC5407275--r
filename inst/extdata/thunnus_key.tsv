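# Diagnostic character key for tuna (Thunnus) COI barcodes: species-specific
# nucleotide states at 14 fixed 1-based positions in the barcode alignment
# frame. Only the three distinct published profiles are shipped; the full
# 8-species key can be supplied by the user in the same format.
# (the common "T. obsesus" misspelling is corrected to Thunnus obesus.)
species	262	268	271	286	313	337	358	400	409	475	478	484	508	535
Thunnus albacares	C	C	C	C	A	C	G	T	A	T	T	G	A	C
Thunnus alalunga	C	T	C	C	G	C	A	T	A	T	C	A	A	T
Thunnus obesus	C	C	C	T	A	C	G	G	A	T	T	G	A	C
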
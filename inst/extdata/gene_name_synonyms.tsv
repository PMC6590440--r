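# Gene-symbol normalization table, v1.
# GenBank records are inconsistent; aliases map to the catalog convention.
alias	canonical
psbA1	psbA
rps12a	rps12
rps12b	rps12
ycf2a	ycf2n
ycf2b	ycf2c
trnM-fCAU	trnfM-CAU
trnfM	trnfM-CAU
lhbA	psbZ
ycf9	psbZ
orf94	ycf94
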
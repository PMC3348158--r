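species	genus	family	order	status
t001	gen0001	fam001	ord01	native
t002	gen0002	fam001	ord01	native
t003	gen0003	fam001	ord01	native
t004	gen0004	fam002	ord01	endemic
t005	gen0005	fam003	ord01	native
t006	gen0006	fam004	ord01	endemic
t007	gen0007	fam004	ord01	native
t008	gen0007	fam004	ord01	native
t009	gen0008	fam004	ord01	exotic
t010	gen0009	fam004	ord01	endemic
t011	gen0010	fam005	ord01	outgroup
t012	gen0010	fam005	ord01	exotic
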
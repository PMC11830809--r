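name	formula	half_reaction	ne_override	mass_g_per_mol	role
formic acid	CH2O2	NA	NA	46.025	both
acetic acid	C2H4O2	NA	NA	60.052	product
propionic acid	C3H6O2	NA	NA	74.079	product
butyric acid	C4H8O2	NA	NA	88.106	product
isobutyric acid	C4H8O2	NA	NA	88.106	product
lactic acid	C3H6O3	NA	NA	90.078	product
succinic acid	C4H6O4	NA	NA	118.088	product
4-methylvaleric acid	C6H12O2	NA	NA	116.158	product
sodium formate	NA	formate_salt	2	68.007	donor
hydrogen	NA	h2_oxidation	2	2.016	donor
thiosulfate	NA	thiosulfate_to_sulfate	8	112.13	donor
sulfate	NA	sulfate_acceptor	8	96.06	acceptor
iron(III)	NA	fe3_to_fe2	1	55.845	acceptor
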
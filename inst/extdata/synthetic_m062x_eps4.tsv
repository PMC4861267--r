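species	isotope	epsilon	energy_kcal	method
ligand	H	78.36	-10.36	M06-2X
ligand	D	78.36	-10.36	M06-2X
water_pentamer	H	78.36	-12.55	M06-2X
water_pentamer	D	78.36	-12.55	M06-2X
ligand_water_cluster	H	78.36	-90.36	M06-2X
ligand_water_cluster	D	78.36	-90.30	M06-2X
receptor	H	4	-450.00	M06-2X
receptor	D	4	-450.00	M06-2X
complex	H	4	-500.00	M06-2X
complex	D	4	-500.45	M06-2X
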
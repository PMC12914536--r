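Endothelial	Literature-standard retinal EC markers (not study-verbatim; editable default)	Pecam1	Cdh5	Cldn5	Egfl7
Rod	Rod photoreceptor markers	Rho	Nrl	Gnat1	Pde6b
Bipolar	Bipolar cell markers	Vsx2	Grm6	Prkca
Muller	Muller glia markers	Glul	Rlbp1	Slc1a3
Microglia	Microglia markers	Cx3cr1	C1qa	Tmem119
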
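# Nuclear g-factors for isotropic hyperfine couplings.
# g_factor = mu/(I*mu_N) sign convention; values from standard nuclear moment
# compilations (Stone, Table of Nuclear Magnetic Dipole Moments, 2005/2014).
isotope,element,spin,g_factor
1H,H,0.5,5.58569468
13C,C,0.5,1.40482360
14N,N,1.0,0.40376100
17O,O,2.5,-0.75751600
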
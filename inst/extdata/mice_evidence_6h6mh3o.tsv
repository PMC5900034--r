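# Illustrative (synthetic) per-kind split of the 24 identification-information
# bits tallied across the two tautomers of 6-hydroxy-6-methylheptan-3-one;
# only the total (24 bits over 8 carbons, MICE = 3.0) is anchored to the
# published identification. The per-kind breakdown below is a reconstruction
# for demonstration and is user-overridable.
kind	bits
1H_shift	4
13C_shift	5
multiplicity	3
J_coupling	2
HSQC_correlation	3
HMBC_correlation	3
TOCSY_COSY_correlation	2
spike_in	2
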
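# Semi-classical two-body dispersion parameters for water (H, O).
# Fixed effective pairwise C6 coefficients and element multipole ratios Q
# (C8ab = 3 C6ab sqrt(Qa Qb)) transcribed by the package authors from
# published D3/D4 tabulations at water-like coordination; Becke-Johnson
# damping constants (a1, a2) and default scaling factors per functional.
# Charge- and coordination-dependent coefficient machinery is out of scope:
# externally computed component tables are the high-fidelity ingestion path.
# units: au
element H q=4.029450
element O q=6.726848
pair H H c6=3.0886
pair H O c6=5.6860
pair O O c6=10.3708
functional BLYP s6=1.0 s8=2.34076671 a1=0.44488865 a2=4.09330090
functional B3LYP s6=1.0 s8=2.02929367 a1=0.40868035 a2=4.53807137
functional PBE s6=1.0 s8=0.95948085 a1=0.38574991 a2=4.80688534
functional PBE0 s6=1.0 s8=1.20065498 a1=0.40085597 a2=5.02928789
functional revPBE s6=1.0 s8=1.74676041 a1=0.53649378 a2=3.07261485
functional revPBE0 s6=1.0 s8=1.57185414 a1=0.38705966 a2=4.11028876
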
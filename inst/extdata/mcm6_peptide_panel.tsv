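sequence	start	end	charge	mz_observed	reproducible	note
YLQLAEELIRPER	46	58	3	543.97	TRUE
DFYVAFQDLPTR	109	120	2	736.87	FALSE	observed +0.5 at z=2 vs computed 736.36; unannotated +1 Da variant suspected
IQETQAELPR	208	217	2	592.82	TRUE
VSGVDGYETEGIR	270	282	2	691.33	TRUE
GDINVCIVGDPSTAK	388	402	2	773.38	TRUE	carbamidomethyl-C fixed
TSILAAANPISGHYDR	497	512	3	562.63	TRUE
ESEDFIVEQYK	589	599	2	693.83	FALSE	computes 693.82 at z=2, ~7 ppm off despite 0 ppm report
ISNLIVLHLR	723	732	3	793.25	FALSE	inconsistent with any charge of the unmodified sequence
SELVNWYLK	746	754	2	576.31	TRUE
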
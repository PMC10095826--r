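# Experimental and computed CB8-guest binding affinities, kcal/mol.
# Guests: G1 methamphetamine, G2 fentanyl, G3 morphine, G4 hydromorphone,
# G5 ketamine (protonated and deprotonated forms, shared experimental value),
# G6 phencyclidine, G7 cocaine.
# Computed columns: bonded parameter sets GAFF, GAFF2 and the force-matched
# FM-PM6 and FM-BLYP sets (RESP charges throughout); SD columns are
# block-analysis standard errors of the free-energy estimates.
# Values packaged verbatim at the published one-decimal precision.
guest	variant	dG_exp	dG_GAFF	sd_GAFF	dG_GAFF2	sd_GAFF2	dG_FMPM6	sd_FMPM6	dG_FMBLYP	sd_FMBLYP
G1		-7.05	-5.9	0.4	-8.0	0.4	-7.4	0.4	-7.4	0.4
G2		-9.93	-8.2	0.5	-11.3	0.5	-9.1	0.5	-10.0	0.5
G3		-11.63	-14.9	0.4	-8.5	0.5	-8.6	0.5	-11.4	0.4
G4		-11.22	-9.9	0.5	-5.5	0.5	-6.6	0.4	-14.7	0.4
G5	prot	-12.32	-3.5	0.5	-8.3	0.5	-6.4	0.5	-9.2	0.5
G5	deprot	-12.32	-10.4	0.5	-10.9	0.5	-8.0	0.5	-16.0	0.5
G6		-14.07	-12.4	0.5	-14.1	0.5	-12.8	0.5	-11.0	0.4
G7		-7.92	-8.1	0.5	-6.9	0.4	-9.2	0.5	-8.2	0.4
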
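# Component reference library: chemical formula, molecular volume and
# labile-hydrogen count for the membrane/protein/substrate species used in
# the supported-bilayer models. Users may edit or supply their own table.
#
# Volumes: lipid fragment volumes follow Armen, Uitto & Feller,
# Biophys J 75 (1998) 734 (PC headgroup 319 A^3; POPC acyl chains 937 A^3);
# cardiolipin split derived from tetraoleoyl CL partial molecular volume
# (~2425 A^3, Kooijman et al.). Protein entries are on a per-mean-residue
# basis (composition-averaged amino acid, ~137 A^3/residue, Harpaz et al.).
#
# formula: total composition of the protiated species; D sites written
#   explicitly (e.g. tail-deuterated chains). Fractional counts allowed
#   (mean-residue entries).
# exchangeable_h: how many of the formula's H are labile (solvent-exchange).
# deuteration: fraction of the NON-labile H biosynthetically replaced by D.
# exchange_fraction: default fraction of labile H that actually exchanges.
name	formula	volume	exchangeable_h	deuteration	exchange_fraction	notes
water	H2O	30.0	0	0	1.0	solvent reference molecule
silicon	Si	20.0	0	0	1.0	crystalline substrate
silica	SiO2	45.4	0	0	1.0	amorphous native oxide
pc_headgroup	C10H18NO8P	319	0	0	1.0	phosphocholine headgroup + glycerol backbone
popc_tails	C32H64	937	0	0	1.0	palmitoyl + oleoyl acyl chains
d_popc_tails	C32H1D63	937	0	0	1.0	tail-deuterated (d63) acyl chains
cl_headgroup	C13H10O17P2	465	1	0	1.0	tetraoleoyl cardiolipin headgroup; central glycerol OH labile
cl_tails	C68H132	1960	0	0	1.0	four oleoyl acyl chains
h_bax	C4.9H7.8N1.4O1.5S0.05	137	1.6	0	0.9	hydrogenous Bax, per mean residue
d_bax	C4.9H7.8N1.4O1.5S0.05	137	1.6	0.9	0.9	deuterated (90%) Bax, per mean residue
h_bcl2	C4.9H7.8N1.4O1.5S0.05	137	1.6	0	0.9	hydrogenous Bcl-2, per mean residue
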
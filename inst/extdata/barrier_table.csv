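species,site,step,barrier_kJ_mol,rank,qualifier,provenance
Glc,reducing_end,RO,200,NA,upper_bound,"ring-opening via O5-C1 cleavage, typically below 200 kJ/mol"
Glc,reducing_end,m1_2,165,NA,,"1,2-hydrogen shift after ring opening"
Glc,reducing_end,m1_3,163,NA,not_in_shift_set,"1,3-hydrogen shift after ring opening (not part of the enumerated shift set)"
Glc,reducing_end,m1_4,203,1,,"O4/C4 -> O1 hydrogen shift"
Glc,reducing_end,m1_5,195,2,,"O5/C5 -> O1 hydrogen shift"
Glc,reducing_end,m1_6,201,3,,"O6/C6 -> O1 hydrogen shift"
Glc,reducing_end,r6,NA,NA,no_value,"direct cross-ring via O3->O5 hydrogen transfer, no ring opening"
Glc,reducing_end,r7,300,NA,gt_300,"simultaneous triple C-C cleavage, no hydrogen transfer"
Glc,reducing_end,r8,300,NA,gt_300,"simultaneous triple C-C cleavage, no hydrogen transfer"
Man-OMe,non_reducing_end,RO1p,231,1,,"ring opening analogue, hydrogen shift toward O5 (reaction 9)"
Man-OMe,non_reducing_end,c0p3p,232,2,,"direct cross-ring cleavage (reaction 10)"
Man-OMe,non_reducing_end,RO2p,257,3,,"ring opening analogue (reaction 12)"
Man-OMe,non_reducing_end,r11,300,NA,gt_300,"hydrogen shift toward O5 (reaction 11)"
Man-OMe,non_reducing_end,r13,300,NA,gt_300,"hydrogen shift toward O5 (reaction 13)"
Man1-2Man,reducing_end,c2,152,1,,"retro-aldol C2-C3 cleavage after ring opening, major fragment"
Man1-2Man,reducing_end,m1_4,161,2,order_inferred,"hydrogen-shift-driven cleavage; 161/172/190 assigned to m1_4/m1_5/m1_6 by sentence order"
Man1-2Man,reducing_end,m1_5,172,3,order_inferred,"hydrogen-shift-driven cleavage; 161/172/190 assigned to m1_4/m1_5/m1_6 by sentence order"
Man1-2Man,reducing_end,m1_6,190,4,order_inferred,"hydrogen-shift-driven cleavage; 161/172/190 assigned to m1_4/m1_5/m1_6 by sentence order"
Man1-3Man,reducing_end,m1_5,NA,1,rank_only,"lowest TS energy of the shift reactions"
Man1-3Man,reducing_end,m1_2,NA,2,rank_only,"second-lowest TS energy; dominates via fewer steps and accessibility"
Man1-3Man,reducing_end,m1_6,NA,3,rank_only,"third-lowest TS energy"
Man1-3Man,reducing_end,m1_4,NA,4,rank_only,"highest TS energy of the shift reactions"
Man1-3Man,non_reducing_end,RO1p,218,1,,"non-reducing-end ring-opening analogue"
Man1-3Man,non_reducing_end,c0p3p,225,2,,"non-reducing-end direct cross-ring cleavage"
Man1-3Man,non_reducing_end,RO2p,254,3,,"non-reducing-end ring-opening analogue"
Man1-4Man,reducing_end,c2,NA,1,rank_only,"lowest TS energy"
Man1-4Man,reducing_end,m1_2,NA,2,rank_only,"relatively low TS energy, two extra isomerization steps"
Man1-4Man,reducing_end,m1_5,178,3,,"TS energies of m1_5 and m1_6 similar"
Man1-4Man,reducing_end,m1_6,178,4,,"TS energies of m1_5 and m1_6 similar"
Man1-4Man,non_reducing_end,RO1p,226,1,,"non-reducing-end ring-opening analogue"
Man1-4Man,non_reducing_end,c0p3p,240,2,,"non-reducing-end direct cross-ring cleavage"
Man1-4Man,non_reducing_end,RO2p,247,3,,"non-reducing-end ring-opening analogue"
GlcNAc1-2Man,reducing_end,c2,156,1,,"lowest TS energy, major fragment"
GlcNAc1-2Man,reducing_end,m1_6,163,2,,"leads to the two-carbon neutral loss"
GlcNAc1-2Man,reducing_end,m1_5,168,3,,"leads to the three-carbon neutral loss"
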
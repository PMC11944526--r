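# Literature reference: intramolecular O1-H...O=C hydrogen bond of luteolin
# and associated ground-state geometry values (M06-2X/6-311++G(d,p)).
# rho/lap/h in a.u., distances in Angstrom, energies in kcal/mol.
quantity,value
rho,0.0425
lap,0.1373
h,-0.0034
ratio,1.1
distance_angstrom,1.739
be_printed_kcal,-8.7
oh_bound_angstrom,0.9843
oh_unbound_angstrom,0.9669
conformer_gap_kcal,5.39
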
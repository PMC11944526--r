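# Solvent series used for the implicit-solvation (SMD) calculations, with
# dielectric constants (metadata for descriptor reports).
solvent,dielectric
water,78.3553
dmso,46.826
methanol,32.613
acetone,20.493
dcm,8.93
thf,7.4257
diethyl_ether,4.2400
benzene,2.2706
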
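# Promolecular single-exponential radial parameters:
# rho_elem(r) = amplitude * exp(-r/decay), amplitude in electrons/Bohr^3,
# decay in Bohr. Packaged constants giving chemically sensible relative
# magnitudes for desk-scale analytic densities; not fitted physics claims.
element,amplitude,decay
H,0.2815,0.529
C,33.4,0.174
N,51.3,0.154
O,74.8,0.139
S,215.0,0.101
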
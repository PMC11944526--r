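# Literature reference: free-radical scavenging thermodynamic descriptors
# (kcal/mol, M06-2X/6-311++G(d,p)). For luteolin, bde_no_water is the
# implicit-water BDE and bde_water the BDE with explicitly coordinated water
# molecules; comparison antioxidants have a single BDE column.
# Data-consistency note carried with the table: on every row
# (pa_ete - bde_no_water) = 2.989 kcal/mol within printed rounding, while
# ip_pde exceeds pa_ete by a constant 0.071 on the luteolin rows although the
# two sums are algebraically identical for a single consistent enthalpy
# ledger; BHT and TBHQ show (ip_pde - bde) offsets of 8.825 and 14.317,
# flagged as anomalies of the printed table, not corrected.
compound,site,bde_no_water,bde_water,ip_pde,pa_ete
luteolin,O1H,88.072,88.681,91.133,91.061
luteolin,O2H,92.153,93.544,95.213,95.142
luteolin,O3H,80.662,82.757,83.722,83.651
luteolin,O4H,83.605,82.096,86.665,86.594
BHA,O1H,77.161,NA,80.213,80.150
BHT,O1H,76.690,NA,85.515,79.679
GA,O1H,84.056,NA,87.118,87.045
GA,O2H,81.193,NA,84.255,84.182
PG,O1H,82.836,NA,85.897,85.825
PG,O2H,78.963,NA,82.025,81.952
PY,O1H,81.331,NA,84.388,84.320
PY,O2H,78.040,NA,81.098,81.029
TBHQ,O1H,77.459,NA,91.776,80.447
TBHQ,O2H,78.548,NA,92.866,81.537
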
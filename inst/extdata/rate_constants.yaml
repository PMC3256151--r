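# Mass-action rate constants for the tissue factor pathway reaction network,
# transcribed from Hockin MF, Kalafatis M, Everse SJ, Mann KG (2002),
# "A model for the stoichiometric regulation of blood coagulation",
# J Biol Chem 277:18322-18333 (Table 2 therein).
#
# Units: second-order association / catalytic-transfer constants in 1/(M*s);
# first-order dissociation / catalytic constants in 1/s. One key per reaction
# arrow of the network (reversible steps appear as an _on/_off pair).

# TF + fVII binding (2nd order on, 1st order off)
tf_vii_on:        3.2e6     # 1/(M*s)
tf_vii_off:       3.1e-3    # 1/s
# TF + fVIIa binding
tf_viia_on:       2.3e7     # 1/(M*s)
tf_viia_off:      3.1e-5    # 1/s
# fVII activation by TF:VIIa, fXa, and thrombin (2nd order)
viia_from_tf_viia:  4.4e5   # 1/(M*s)
viia_from_xa:       1.3e7   # 1/(M*s)
viia_from_iia:      2.3e4   # 1/(M*s)
# Extrinsic tenase acting on fX (Michaelis complex on/off, then catalysis)
tf_viia_x_on:     2.5e7     # 1/(M*s)
tf_viia_x_off:    1.05      # 1/s
tf_viia_x_cat:    6.0       # 1/s  (TF:VIIa:X -> TF:VIIa:Xa)
# Product complex TF:VIIa:Xa association/dissociation
tf_viia_xa_on:    2.2e7     # 1/(M*s)
tf_viia_xa_off:   19.0      # 1/s
# Extrinsic tenase acting on fIX
tf_viia_ix_on:    1.0e7     # 1/(M*s)
tf_viia_ix_off:   2.4       # 1/s
tf_viia_ix_cat:   1.8       # 1/s  (releases fIXa)
# fII activation by free fXa (slow, 2nd order)
iia_from_xa:      7.5e3     # 1/(M*s)
# fVIII activation by thrombin
viiia_from_iia:   2.0e7     # 1/(M*s)
# Intrinsic tenase assembly fVIIIa + fIXa
ixa_viiia_on:     1.0e7     # 1/(M*s)
ixa_viiia_off:    5.0e-3    # 1/s
# Intrinsic tenase acting on fX
ixa_viiia_x_on:   1.0e8     # 1/(M*s)
ixa_viiia_x_off:  1.0e-3    # 1/s
ixa_viiia_x_cat:  8.2       # 1/s
# fVIIIa A2-domain dissociation (VIIIa <-> VIIIa1-L + VIIIa2)
viiia_diss:       6.0e-3    # 1/s
viiia_assoc:      2.2e4     # 1/(M*s)
# Spontaneous decay of VIIIa-containing complexes via A2 loss
ixa_viiia_x_decay: 1.0e-3   # 1/s (IXa:VIIIa:X -> VIIIa1-L + VIIIa2 + X + IXa)
ixa_viiia_decay:   1.0e-3   # 1/s (IXa:VIIIa -> VIIIa1-L + VIIIa2 + IXa)
# fV activation by thrombin
va_from_iia:      2.0e7     # 1/(M*s)
# Prothrombinase assembly fXa + fVa
xa_va_on:         4.0e8     # 1/(M*s)
xa_va_off:        0.2       # 1/s
# Prothrombinase acting on fII (Michaelis complex, then meizothrombin)
xa_va_ii_on:      1.0e8     # 1/(M*s)
xa_va_ii_off:     103.0     # 1/s
xa_va_ii_cat:     63.5      # 1/s  (-> mIIa)
# Meizothrombin conversion to thrombin by prothrombinase
miia_to_iia:      1.5e7     # 1/(M*s)
# TFPI inhibition of fXa
xa_tfpi_on:       9.0e5     # 1/(M*s)
xa_tfpi_off:      3.6e-4    # 1/s
# TFPI inhibition of the TF:VIIa:Xa product complex
tf_viia_xa_tfpi_on:  3.2e8  # 1/(M*s)
tf_viia_xa_tfpi_off: 1.1e-4 # 1/s
# Quaternary complex from preformed Xa:TFPI
tf_viia_plus_xa_tfpi: 5.0e7 # 1/(M*s)
# Antithrombin (irreversible, 2nd order)
xa_at:            1.5e3     # 1/(M*s)
miia_at:          7.1e3     # 1/(M*s)
ixa_at:           4.9e2     # 1/(M*s)
iia_at:           7.1e3     # 1/(M*s)
tf_viia_at:       2.3e2     # 1/(M*s)
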
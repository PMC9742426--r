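data_synthetic_example
# synthetic assigned-shift loop in minimal NMR-STAR layout
save_assigned_chem_shift_list_1
loop_
_Atom_chem_shift.Seq_ID
_Atom_chem_shift.Atom_ID
_Atom_chem_shift.Val
_Atom_chem_shift.Val_err
1 CA 55.12 0.30
1 CB 29.88 0.35
1 C  175.30 0.25
1 N  119.70 0.40
1 H  8.21 0.05
1 HA 4.32 0.05
2 CA 58.40 0.30
2 CG 30.00 0.35
stop_
save_
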
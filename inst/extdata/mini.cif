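data_mini
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N  . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 90.00 ? 1 ALA A N  1
ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 90.00 ? 1 ALA A CA 1
ATOM 3 C CA . GLY A 1 2 ? 12.345 2.500 -4.000 1.00 85.50 ? 2 GLY A CA 1
ATOM 4 N N  . LEU A 1 3 ? 13.000 1.000 -2.000 1.00 70.00 ? 3 LEU A N  1
ATOM 5 C CA . LEU A 1 3 ? 13.500 0.500 -1.000 1.00 70.00 ? 3 LEU A CA 1
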
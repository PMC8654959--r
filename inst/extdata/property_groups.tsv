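# Physicochemical group-membership table backing the 31-bit per-residue encoding.
# One line per group: group_id <TAB> segment <TAB> member residues.
#   segment "overlap"            : one of the 10 (possibly overlapping) residue classes -> bits 1-10
#   segment "attribute:<name>:<i>": group i (1-3) of a three-way partition attribute    -> bits 11-31
# The 10 overlapping classes follow the classic Taylor-style physicochemical Venn
# classification (hydrophobic/polar/small/tiny/aliphatic/aromatic/charged/positive/
# negative) extended with the hydroxyl-bearing residues.  The seven attributes are the
# canonical three-group composition/transition/distribution (CTD) tables of Dubchak et
# al. (polarity, normalized Van der Waals volume, hydrophobicity, secondary structure,
# solvent accessibility, charge, polarizability).  Edit or replace freely: the loader
# enforces only the structural rules (10 overlap groups; 7 attributes whose 3 groups
# partition the 20 canonical residues) and the 31-bit layout.
hydrophobic	overlap	ACFGHIKLMTVWY
polar	overlap	CDEHKNQRSTWY
small	overlap	ACDGNPSTV
tiny	overlap	ACGS
aliphatic	overlap	ILV
aromatic	overlap	FHWY
charged	overlap	DEHKR
positive	overlap	HKR
negative	overlap	DE
hydroxylic	overlap	STY
polarity_low	attribute:polarity:1	LIFWCMVY
polarity_medium	attribute:polarity:2	PATGS
polarity_high	attribute:polarity:3	HQRKNED
vdw_small	attribute:vdw_volume:1	GASTPDC
vdw_medium	attribute:vdw_volume:2	NVEQIL
vdw_large	attribute:vdw_volume:3	MHKFRYW
hydro_polar	attribute:hydrophobicity:1	RKEDQN
hydro_neutral	attribute:hydrophobicity:2	GASTPHY
hydro_hydrophobic	attribute:hydrophobicity:3	CLVIMFW
ss_helix	attribute:secondary_structure:1	EALMQKRH
ss_strand	attribute:secondary_structure:2	VIYCWFT
ss_coil	attribute:secondary_structure:3	GNPSD
sa_buried	attribute:solvent_accessibility:1	ALFCGIVW
sa_exposed	attribute:solvent_accessibility:2	RKQEND
sa_intermediate	attribute:solvent_accessibility:3	MSPTHY
charge_positive	attribute:charge:1	KR
charge_neutral	attribute:charge:2	ANCQGHILMFPSTWYV
charge_negative	attribute:charge:3	DE
polz_low	attribute:polarizability:1	GASDT
polz_medium	attribute:polarizability:2	CPNVEQIL
polz_high	attribute:polarizability:3	KMHFRYW
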
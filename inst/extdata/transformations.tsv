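name	exact_mass	formula	group
glycine_residue	57.021464	C2H3NO	3
alanine_residue	71.037114	C3H5NO	3
serine_residue	87.032028	C3H5NO2	3
proline_residue	97.052764	C5H7NO	3
valine_residue	99.068414	C5H9NO	3
threonine_residue	101.047678	C4H7NO2	3
cysteine_residue	103.009184	C3H5NOS	1
leucine_residue	113.084064	C6H11NO	3
asparagine_residue	114.042927	C4H6N2O2	3
aspartate_residue	115.026943	C4H5NO3	3
glutamine_residue	128.058578	C5H8N2O2	3
lysine_residue	128.094963	C6H12N2O	3
glutamate_residue	129.042593	C5H7NO3	3
methionine_residue	131.040485	C5H9NOS	1
histidine_residue	137.058912	C6H7N3O	3
phenylalanine_residue	147.068414	C9H9NO	3
arginine_residue	156.101111	C6H12N4O	3
tyrosine_residue	163.063329	C9H9NO2	3
tryptophan_residue	186.079313	C11H10N2O	3
adenine	135.054495	C5H5N5	2
guanine	151.049410	C5H5N5O	3
cytosine	111.043262	C4H5N3O	3
thymine	126.042927	C5H6N2O2	3
uracil	112.027277	C4H4N2O2	3
water	18.010565	H2O	4
methylene	14.015650	CH2	NA
oxygen	15.994915	O	4
carbonyl	27.994915	CO	4
carbon_dioxide	43.989829	CO2	4
formaldehyde	30.010565	CH2O	4
acetyl	42.010565	C2H2O	4
ammonia	17.026549	NH3	2
acetate	60.021129	C2H4O2	4
urea	60.032363	CH4N2O	3
hexose_residue	162.052823	C6H10O5	4
pentose_residue	132.042259	C5H8O4	4
deoxyhexose_residue	146.057909	C6H10O4	4
sulfur_trioxide	79.956815	SO3	1
hydrogen_sulfide	33.987721	H2S	1
glyoxylate	74.000394	C2H2O3	4
allantoin	158.043990	C4H6N4O3	3
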
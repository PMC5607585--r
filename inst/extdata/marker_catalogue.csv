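# MR-conditional biopsy marker catalogue: the 14 markers studied (6 Gold
# Anchor configurations, 5 Visicoil, 3 BiomarC), identified by brand and
# width x length in mm. Ball-configured Gold Anchor markers are the linear
# ones re-folded (0.28x10 -> 1.3x1.3, 0.28x20 -> 1.8x1.8, 0.4x20 -> 2.1x2.1).
# Apparent-size factors are the cohort means (x4.2 width, x2 length) except
# for Visicoil 1.1x10 whose measured apparent widths anchor them
# (3.5 mm parallel to B0, 6.5 mm orthogonal). One Visicoil is brass rather
# than gold; the available documentation does not identify which; all are recorded as gold.
name,brand,material,shape,width_mm,length_mm,apparent_width_factor,apparent_length_factor,orthogonal_width_factor
Gold Anchor 0.28x10,Gold Anchor,gold_iron,cylinder,0.28,10,4.2,2,NA
Gold Anchor 0.28x20,Gold Anchor,gold_iron,cylinder,0.28,20,4.2,2,NA
Gold Anchor 0.4x20,Gold Anchor,gold_iron,cylinder,0.4,20,4.2,2,NA
Gold Anchor 1.3x1.3,Gold Anchor,gold_iron,sphere,1.3,1.3,4.2,2,NA
Gold Anchor 1.8x1.8,Gold Anchor,gold_iron,sphere,1.8,1.8,4.2,2,NA
Gold Anchor 2.1x2.1,Gold Anchor,gold_iron,sphere,2.1,2.1,4.2,2,NA
Visicoil 0.35x5,Visicoil,gold,cylinder,0.35,5,4.2,2,NA
Visicoil 0.35x30,Visicoil,gold,cylinder,0.35,30,4.2,2,NA
Visicoil 0.5x5,Visicoil,gold,cylinder,0.5,5,4.2,2,NA
Visicoil 0.75x10,Visicoil,gold,cylinder,0.75,10,4.2,2,NA
Visicoil 1.1x10,Visicoil,gold,cylinder,1.1,10,3.18,1,5.91
BiomarC 1x3,BiomarC,carbon_coated,cylinder,1,3,4.2,2,NA
BiomarC 1x5,BiomarC,carbon_coated,cylinder,1,5,4.2,2,NA
BiomarC 2x4,BiomarC,carbon_coated,cylinder,2,4,4.2,2,NA
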
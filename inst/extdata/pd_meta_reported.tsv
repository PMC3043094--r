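pathway	p_meta	p_corrected
Axon guidance	1.39E-09	2.79E-07
Focal adhesion	3.82E-08	7.68E-06
Calcium signaling pathway	1.42E-07	2.85E-05
Cell adhesion molecules (CAMs)	1.04E-06	2.09E-04
Adherens junction	1.18E-06	2.37E-04
Renal cell carcinoma	2.70E-06	5.43E-04
Regulation of actin cytoskeleton	1.35E-05	2.71E-03
Non-small cell lung cancer	8.40E-05	1.69E-02
Melanogenesis	9.59E-05	1.93E-02
ErbB signaling pathway	1.15E-04	2.31E-02
Long-term potentiation	2.62E-04	5.27E-02
Glioma	2.71E-04	5.44E-02
Type I diabetes mellitus	3.53E-04	7.10E-02
Pancreatic cancer	6.28E-04	1.26E-01
Phosphatidylinositol signaling system	6.98E-04	1.40E-01
Neuroactive ligand-receptor interaction	1.31E-03	2.63E-01
Complement and coagulation cascades	1.39E-03	2.79E-01
Heparan sulfate biosynthesis	1.62E-03	3.25E-01
MAPK signaling pathway	1.71E-03	3.43E-01
Endometrial cancer	2.86E-03	5.75E-01
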
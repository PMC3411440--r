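dataset	promethee2	topsis	wsm	n_classes
breast_cancer	2	2	2	2
breast_tissue	6	6	6	6
acute_inflammations	2	4	4	2
ecoli	4	3	3	8
glass	8	2	2	6
habermans_survival	2	2	2	2
ionosphere	2	2	2	2
iris	2	2	2	3
parkinsons	5	3	3	2
pima_indians_diabetes	2	2	2	2
sonar	2	2	2	2
transfusion	2	2	2	2
wine	3	3	3	3
wine_quality_red	6	6	3	6
yeast	10	9	9	10
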
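dataset	dunn	silhouette	pbm	hubert	norm_hubert	db	sd	s_dbw	cs	c_index	n_classes
breast_cancer	5	2	2	2	2	10	2	10	2	5	2
breast_tissue	3	2	6	2	2	3	2	7	6	10	6
acute_inflammations	4	2	9	2	2	10	4	10	9	4	2
ecoli	3	2	3	2	2	10	4	7	4	4	8
glass	2	2	2	2	2	2	2	10	8	2	6
habermans_survival	8	2	5	2	2	10	4	10	4	10	2
ionosphere	2	2	2	2	3	10	2	9	9	10	2
iris	2	2	2	2	2	2	2	10	2	2	3
parkinsons	3	3	5	2	2	8	3	9	8	10	2
pima_indians_diabetes	2	2	4	2	2	10	3	10	10	10	2
sonar	4	2	2	2	2	10	4	10	4	4	2
transfusion	9/10	2	7	2	2	2	2	10	7	9	2
wine	6	3	3	2	2	3	2	7	3	6	3
wine_quality_red	2	2	3	2	2	9	3	3	3	9	6
yeast	9/10	2	2	2	2	10	3	9	10	10	10
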
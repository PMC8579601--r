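example_id	trait_family	n_snps_tested	beta_primary	se_primary	beta_other	se_other	q	p	p_bound	i2	ci_lo	ci_hi
a	CRF	7	0.040	0.007	0.0163	0.0060	6.58	0.010	NA	84.8	38.0	96.3
b	CRF	7	-0.050	0.008	-0.0271	0.0065	4.86	0.028	NA	79.4	11.1	95.2
c	CRF	7	-0.062	0.011	-0.0281	0.0094	5.34	0.021	NA	81.3	20.3	95.6
d	CRF	7	-0.137	0.024	0.0136	0.0206	22.13	NA	0.001	95.5	86.8	98.5
e	CRF	7	0.010	0.002	0.0038	0.0012	8.37	0.0038	NA	88.1	54.1	96.9
f	CRF	7	0.012	0.002	0.0111	0.0026	0.04	0.83	NA	0.0	NA	NA
g	CRF	7	0.016	0.003	0.0021	0.0040	7.96	0.0048	NA	87.4	51.1	96.8
h	PA	5	-0.436	0.076	-0.0893	0.0916	8.51	0.0035	NA	88.3	55.0	96.9
i	PA	5	-0.308	0.055	0.0503	0.0670	16.98	NA	0.001	94.1	81.4	98.1
j	PA	5	-0.358	0.059	-0.2636	0.0718	1.03	0.31	NA	3.0	NA	NA
k	PA	5	-0.450	0.070	-0.2258	0.0855	4.09	0.043	NA	75.6	0.0	94.5
l	PA	5	-0.700	0.128	0.0542	0.1057	20.63	NA	0.001	95.2	85.5	98.4
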
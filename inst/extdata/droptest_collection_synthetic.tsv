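strain	class	0.00	0.05	0.10	0.15	0.20	0.25	0.30	0.35	0.40
ancestral_01	ancestral	6	4	3	1	0	0	0	0	0
ancestral_02	ancestral	6	4	3	1	0	0	0	0	0
ancestral_03	ancestral	6	4	3	1	0	0	0	0	0
ancestral_04	ancestral	6	5	4	2	1	0	0	0	0
ancestral_05	ancestral	6	4	3	1	0	0	0	0	0
ancestral_06	ancestral	6	4	3	1	0	0	0	0	0
ancestral_07	ancestral	6	4	3	1	0	0	0	0	0
ancestral_08	ancestral	6	4	3	1	0	0	0	0	0
ancestral_09	ancestral	6	4	3	1	0	0	0	0	0
ancestral_10	ancestral	6	4	3	1	0	0	0	0	0
ancestral_11	ancestral	6	5	4	2	1	0	0	0	0
ancestral_12	ancestral	6	4	3	1	0	0	0	0	0
ancestral_13	ancestral	6	4	3	1	0	0	0	0	0
ancestral_14	ancestral	6	4	1	0	0	0	0	0	0
ancestral_15	ancestral	6	5	4	2	1	0	0	0	0
ancestral_16	ancestral	6	4	3	1	0	0	0	0	0
ancestral_17	ancestral	6	4	3	1	0	0	0	0	0
ancestral_18	ancestral	6	4	3	1	0	0	0	0	0
ancestral_19	ancestral	6	4	3	1	0	0	0	0	0
ancestral_20	ancestral	6	4	3	1	0	0	0	0	0
ancestral_21	ancestral	6	4	3	1	0	0	0	0	0
ancestral_22	ancestral	6	4	3	1	0	0	0	0	0
ancestral_23	ancestral	6	4	3	1	0	0	0	0	0
ancestral_24	ancestral	6	4	1	0	0	0	0	0	0
ancestral_25	ancestral	6	4	3	1	0	0	0	0	0
ancestral_26	ancestral	6	4	3	1	0	0	0	0	0
ancestral_27	ancestral	6	4	3	1	0	0	0	0	0
ancestral_28	ancestral	6	4	1	0	0	0	0	0	0
ancestral_29	ancestral	6	4	3	1	0	0	0	0	0
ancestral_30	ancestral	6	4	3	1	0	0	0	0	0
ancestral_31	ancestral	6	5	4	2	1	0	0	0	0
ancestral_32	ancestral	6	4	3	1	0	0	0	0	0
ancestral_33	ancestral	6	4	3	1	0	0	0	0	0
ancestral_34	ancestral	6	4	3	1	0	0	0	0	0
ancestral_35	ancestral	6	4	1	0	0	0	0	0	0
ancestral_36	ancestral	6	4	3	1	0	0	0	0	0
ancestral_37	ancestral	6	4	3	1	0	0	0	0	0
ancestral_38	ancestral	6	4	3	1	0	0	0	0	0
ancestral_39	ancestral	6	5	4	2	1	0	0	0	0
ancestral_40	ancestral	6	4	3	1	0	0	0	0	0
ancestral_41	ancestral	6	4	3	1	0	0	0	0	0
ancestral_42	ancestral	6	4	3	1	0	0	0	0	0
ancestral_43	ancestral	6	4	3	1	0	0	0	0	0
ancestral_44	ancestral	6	4	3	1	0	0	0	0	0
ancestral_45	ancestral	6	4	3	1	0	0	0	0	0
ancestral_46	ancestral	6	4	3	1	0	0	0	0	0
ancestral_47	ancestral	6	4	3	1	0	0	0	0	0
ancestral_48	ancestral	6	4	3	1	0	0	0	0	0
ancestral_49	ancestral	6	4	3	1	0	0	0	0	0
ancestral_50	ancestral	6	4	3	1	0	0	0	0	0
ancestral_51	ancestral	6	4	3	1	0	0	0	0	0
ancestral_52	ancestral	6	4	3	1	0	0	0	0	0
VIIXVI_01	VII^XVI	6	5	5	4	4	3	2	2	1
VIIXVI_02	VII^XVI	6	5	5	4	3	2	2	1	0
VIIXVI_03	VII^XVI	6	5	5	4	4	3	2	2	1
VIIXVI_04	VII^XVI	6	5	5	4	4	3	2	2	1
VIIXVI_05	VII^XVI	6	5	5	4	3	2	2	1	0
VIIXVI_06	VII^XVI	6	5	5	4	3	2	2	1	0
VIIXVI_07	VII^XVI	6	5	5	4	4	3	2	2	1
VIIXVI_08	VII^XVI	6	5	5	4	3	2	2	1	0
VIIXVI_09	VII^XVI	6	5	5	4	4	3	2	2	1
VIIXVI_10	VII^XVI	6	5	5	4	3	2	2	1	0
XIXVI_01	XI^XVI	6	5	5	4	4	3	2	2	1
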
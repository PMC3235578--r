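eq_label	text_eq	reaction_string	dH_g	minus_TdS_g	dG_g	ddG_solv	dG_aq	protons_released_at_pH7	n_H_consumed	is_reduction	known_anomaly
EEq4a	5a	1 + Cu(H2O)5^2+ -> 2a(H2O)2 + 3H2O + H+	480.8	-68.6	412.2	-390.2	-18.0	1	0	FALSE	.
EEq4b	5b	1 + Cu(H2O)5^2+ -> 2b(H2O)2 + 3H2O + H+	533.6	-76.1	457.6	-403.2	14.3	1	0	FALSE	.
EEq4c	5c	1 + Cu(H2O)5^2+ -> 2c(H2O)2 + 3H2O + H+	519.3	-68.8	450.5	-381.4	29.1	1	0	FALSE	.
EEq5	6	3 + Cu(H2O)5 -> 4(H2O) + 4H2O + H+	464.3	-90.6	373.6	-323.4	10.2	1	0	FALSE	.
EEq6a	7a	Im + Cu(H2O)5^2+ -> Cu(Im)(H2O)4^2+ + H2O	-157.3	6.5	-150.8	150.3	-0.5	0	0	FALSE	.
EEq6b	7b	2Im + Cu(H2O)5^2+ -> Cu(Im)2(H2O)3^2+ + 2H2O	-298.4	14.3	-284.1	273.2	-10.9	0	0	FALSE	.
EEq7a	8a	2a(H2O)2 + Im -> 2a(Im)(H2O) + H2O	-105.0	3.9	-101.1	77.0	-24.1	0	0	FALSE	.
EEq7b	8b	1 + Cu(Im)(H2O)4^2+ -> 2a(Im)(H2O) + 3H2O + H+	533.1	-71.2	461.9	-463.5	-41.6	1	0	FALSE	.
EEq8a	9a	2a(Im)(H2O) + Im -> 2a(Im)2 + H2O	-85.5	6.1	-79.4	68.4	-11.0	0	0	FALSE	.
EEq8b	9b	1 + Cu(Im)2(H2O)3^2+ -> 2a(Im)2 + 3H2O + H+	588.7	-72.9	515.8	-517.9	-42.2	1	0	FALSE	.
EEq9a	10a	4(H2O) + Im -> 4(Im) + H2O	-89.8	3.1	-86.7	66.2	-20.5	0	0	FALSE	.
EEq9b	10b	3 + Cu(H2O)5^2+ + Im -> 4(Im) + 5H2O + H+	374.5	-87.5	287.0	-257.3	-10.3	1	0	FALSE	.
EEq10	11	4(Im) + Im -> 4(Im)2	-105.6	35.9	-69.7	76.6	6.9	0	0	FALSE	.
EEq11	12	4(Im) + Im + 1 -> 2a(Im)2 + 3	-84.1	28.8	-55.3	12.5	-42.8	0	0	FALSE	.
EEq12	13	5 + Cu(H2O)5^2+ -> 6(H2O)2 + 3H2O	-300.3	-29.5	-329.8	293.8	-36.0	0	0	FALSE	.
EEq13	14	6(H2O)2 + Im -> 6(Im)(H2O) + H2O	-121.9	9.6	-112.2	99.7	-12.5	0	0	FALSE	.
EEq14	15	6(Im)(H2O) + NMA -> 7 + H2O	68.5	-3.7	64.8	-85.4	-20.5	0	0	FALSE	.
EEq15a	16a	1 + 6(H2O)2 -> 8a + 2H2O + H+	623.3	-44.8	578.4	-535.6	2.8	1	0	FALSE	.
EEq15b	16b	2a(H2O)2 + 5 -> 8a + 2H2O	-157.9	-5.7	-163.6	148.4	-15.2	0	0	FALSE	.
EEq16a	17a	1 + 6(Im)(H2O) -> 9 + H2O + H+	608.0	-8.4	605.8	-543.8	22.0	1	0	FALSE	dG_g_mismatch
EEq16b	17b	9 -> 8a + Im	130.9	-46.0	84.8	-91.5	-6.7	0	0	FALSE	.
EEq16c	17c	9 + H2O + H+ -> 5 + 3a(Im)H2O	-183.7	36.4	-147.3	162.9	-24.4	-1	0	FALSE	direction_sign
EEq17	18	1 + Cu(H2O)3^+ -> 2I(H2O) + 2H2O + H+	869.3	-40.1	829.2	-783.9	5.3	1	0	FALSE	.
EEq18	19	Im + Cu(H2O)3^+ -> Cu(Im)(H2O)+ + 2H2O	-73.2	-16.6	-89.8	73.5	-16.3	0	0	FALSE	.
EEq19a	20a	Im + Cu(Im)(H2O)+ -> Cu(Im)2+ + H2O	-120.1	8.5	-111.6	84.2	-27.4	0	0	FALSE	.
EEq19b	20b	5 + Cu(Im)(H2O)+ -> Cu(Im)(H13H14)+ + H2O	-105.1	-5.2	-110.4	67.0	-43.4	0	0	FALSE	.
EEq19c	20c	5 + Cu(Im)(H2O)+ -> Cu(Im)(H14H13)+ + H2O	-135.9	2.7	-133.2	102.2	-31.1	0	0	FALSE	.
EEq20	21	1 + Cu(Im)(H2O)+ -> 2I(Im) + H2O + H+	854.4	-8.9	845.5	-808.5	-3.0	1	0	FALSE	.
EEq21	22	2I(Im) + Im -> 2I(Im)2	-71.6	33.6	-38.1	60.8	22.7	0	0	FALSE	.
EEq22	23	1 + Cu(Im)2+ -> 2I(Im)2 + H+	902.9	16.2	919.1	-831.9	47.2	1	0	FALSE	.
EEq23	24	5 + Cu(H2O)3^+ -> 6I + 3H2O	-176.3	-23.4	-199.7	126.9	-72.8	0	0	FALSE	.
EEq24a	25a	1 + 6I -> 8aI + H+	993.0	-7.1	985.9	-881.3	64.6	1	0	FALSE	.
EEq24b	25b	1 + 6I -> 8bI + H+	940.3	17.0	957.3	-853.9	63.4	1	0	FALSE	.
EEq25	26	NMA + 6I -> 7I	-59.2	26.0	-33.2	58.2	25.0	0	0	FALSE	.
EEq26	27	Im + 6I -> 6I(Im)	-74.2	27.9	-46.3	56.4	10.1	0	0	FALSE	.
EEq27	28	2a(H2O)2 + e- -> 2aI(H2O) + H2O	-641.7	-42.0	-683.7	215.9	-467.8	0	0	TRUE	.
EEq28	29	2a(Im)(H2O) + e- -> 2I(Im) + H2O	-624.7	-31.4	-656.1	187.8	-468.3	0	0	TRUE	.
EEq29a	30a	2a(Im)2 + 5 + e- + H+ -> 1 + Cu(Im)(H13H14)+	-74.2	27.9	-46.3	56.4	10.1	0	1	TRUE	duplicate_of_EEq26
EEq29b	30b	2a(Im)2 + 5 + e- + H+ -> 1 + Cu(Im)(H14H13)+	-1529.6	-25.9	-1555.4	1030.0	-525.4	0	1	TRUE	.
EEq30	31	2a(Im)2 + 5 + e- + H+ -> 1 + 6I(Im) + Im	-1570.9	-7.4	-1578.3	1037.7	-540.6	0	1	TRUE	.
EEq31	32	2a(Im)2 + 5 + e- + H+ -> 1 + 6I + 2Im	-1496.7	-35.3	-1532.1	981.3	-550.8	0	1	TRUE	.
EEq32	33	6(H2O)2 + e- -> 6I + 2H2O	-906.1	-64.5	-970.6	442.7	-527.9	0	0	TRUE	.
EEq33	34	6(Im)(H2O) + e- -> 6I + Im + H2O	-784.2	-74.1	-858.4	343.0	-515.4	0	0	TRUE	.
EEq34	35	7 + e- -> 6I + Im + NMA	-715.7	-77.8	-793.5	257.6	-535.9	0	0	TRUE	.
EEq35	36	6(Im)(H2O) + e- -> 6I(Im) + H2O	-858.4	-46.2	-904.6	399.4	-505.3	0	0	TRUE	.
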
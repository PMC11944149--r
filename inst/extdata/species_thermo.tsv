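metabolite	species	dfG0	dfH0	z	nH	phase
glc.Ext	glucose(aq)	-915.90	-1262.19	0	12	aqueous
h2o.Ext	H2O(l)	-237.19	-285.83	0	2	aqueous
h2o.Ext	H2O(g)	-228.57	-241.82	0	2	gas
o2.Ext	O2(aq)	16.40	-11.70	0	0	aqueous
o2.Ext	O2(g)	0.00	0.00	0	0	gas
co2.Ext	CO2(aq)	-385.98	-413.80	0	0	aqueous
co2.Ext	HCO3-	-586.77	-691.99	-1	1	aqueous
co2.Ext	CO3-2	-527.81	-677.14	-2	0	aqueous
co2.Ext	CO2(g)	-394.36	-393.50	0	0	gas
ac.Ext	acetate-	-369.31	-486.01	-1	3	aqueous
ac.Ext	acetic.acid	-396.45	-485.76	0	4	aqueous
nh4.Ext	NH4+	-79.31	-132.51	1	4	aqueous
nh4.Ext	NH3(aq)	-26.50	-80.29	0	3	aqueous
po4.Ext	H3PO4	-1142.54	-1288.34	0	3	aqueous
po4.Ext	H2PO4-	-1137.30	-1302.60	-1	2	aqueous
po4.Ext	HPO4-2	-1096.10	-1299.00	-2	1	aqueous
po4.Ext	PO4-3	-1018.70	-1277.40	-3	0	aqueous
so4.Ext	SO4-2	-744.53	-909.27	-2	0	aqueous
so4.Ext	HSO4-	-755.91	-887.34	-1	1	aqueous
bio.Ext	biomass.CH1.6N0.26O0.38P0.023S0.006	-67.00	-91.00	0	1.6	aqueous
h.Ext	H+	0.00	0.00	1	1	aqueous
h	H+	0.00	0.00	1	1	aqueous
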
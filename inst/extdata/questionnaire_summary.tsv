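row	n	mean	sd	q1	q2	q3	q4	q5	q6	q7	q8
All	16	4.20	0.45	3.31	3.75	4.44	4.69	4.38	4.25	4.25	4.50
healthy	6	4.15	0.68	2.83	3.83	4.83	4.83	4.33	3.83	4.00	4.67
healthy/often	3	4.54	0.56	3.33	4.33	5.00	5.00	4.67	4.33	4.67	5.00
healthy/sometimes	2	3.81	0.80	2.50	3.50	4.50	4.50	4.50	3.50	3.00	4.50
healthy/never	1	3.63	1.06	2.00	3.00	5.00	5.00	3.00	3.00	4.00	4.00
stroke	10	4.23	0.37	3.60	3.70	4.20	4.60	4.40	4.50	4.40	4.40
stroke/often	1	3.75	1.04	3.00	2.00	4.00	4.00	3.00	5.00	4.00	5.00
stroke/sometimes	3	4.13	0.56	3.00	3.67	4.00	4.33	4.67	4.67	4.33	4.33
stroke/almost never	1	3.13	0.83	3.00	2.00	2.00	4.00	4.00	3.00	4.00	3.00
stroke/never	5	4.60	0.24	4.20	4.40	4.80	5.00	4.60	4.60	4.60	4.60
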
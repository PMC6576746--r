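template_id	candidate_structure	protein_key	p_value
1SO2	5U09	P21554	4.13e-4
1SO2	1XU9	P28845	4.16e-5
1SO2	3HX3	P12271	5.42e-4
1SO2	1R5L	P49638	3.40e-5
1SO2	3VW7	P25116	6.86e-5
1SO2	3SOA	Q9UQM7	3.66e-4
1SO2	1UW5	Q00169	4.36e-4
1SO2	3K1Z	Q9BSH5	2.63e-4
1SO2	4Q6R	O95470	3.62e-4
1SO2	4OQA	P09874	3.47e-6
1SO2	2OBD	P11597	1.43e-3
1SO2	2CW6	P35914	1.36e-3
1SO2	4OQV	Q02127	3.29e-4
1SO2	5KDI	Q96JA3	9.93e-4
1SO2	4FC7	Q9NUI1	1.36e-3
1SO2	4OTP	Q9BRS2	1.45e-3
1SO2	5HZ8	P15090	1.08e-3
1SO2	4P8V	Q15782	6.65e-4
1SO2	5FYQ	P62826	2.64e-4
1SO2	2ONI	Q96PU5	1.03e-3
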
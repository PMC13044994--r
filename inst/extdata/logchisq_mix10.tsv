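r	w	m	v
 1	5.3994764978205325e-03	-9.8322117168106509e+00	1.4351615288570480e+01
 2	4.0576935538662914e-02	-6.3552029708120177e+00	5.9316366463806451e+00
 3	1.2608781297080149e-01	-3.8041025608951777e+00	2.8840499115988929e+00
 4	1.8542520559105058e-01	-2.2108204880439448e+00	1.3436887607824144e+00
 5	1.3578539473018225e-01	-1.2688587102512374e+00	6.5888620055951408e-01
 6	1.1750661422454643e-01	-6.0617256618284276e-01	5.3588225561082692e-01
 7	1.1461527160195850e-01	-1.3859393453849975e-01	4.2537703819784495e-01
 8	1.1218403283972923e-01	 2.1496596680293426e-01	3.1764031973229523e-01
 9	1.0201704115582599e-01	 7.8526516019976433e-01	2.1331183006435522e-01
10	6.0402214849422139e-02	 1.4146893098816955e+00	2.0127410241177995e-01
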
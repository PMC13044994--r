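r	w	m	v
 1	7.4940759805825014e-02	-1.0846479435124190e+00	1.4379691906507291e-01
 2	1.0087801717303660e-01	-6.4589673531480485e-01	1.2297820034121559e-01
 3	1.0453372773592273e-01	-3.0815053964919470e-01	1.5913032826515558e-01
 4	1.0617523968195754e-01	-5.4389022868812920e-02	1.5016272252413104e-01
 5	1.0605818161731764e-01	 2.4445282164439308e-01	1.9814682675446973e-01
 6	1.1482646251360537e-01	 5.9695865402747550e-01	2.0376943625876542e-01
 7	1.4983646746712975e-01	 1.1177162797837443e+00	3.6401729046001302e-01
 8	1.8047642167159364e-01	 1.6905973950425701e+00	9.5481466140042792e-01
 9	5.6463405678803785e-02	 2.9551807378872867e+00	1.9419354922496792e+00
10	5.8113166548079713e-03	 4.7698153651588679e+00	4.3491735659871935e+00
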
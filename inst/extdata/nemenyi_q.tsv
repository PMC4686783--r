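# Nemenyi critical values q_alpha for k treatments
# q_alpha = (infinite-df studentized range quantile) / sqrt(2),
# the standard critical values for the Nemenyi post-hoc test.
k	q_0.05	q_0.10
2	1.9600	1.6449
3	2.3437	2.0523
4	2.5690	2.2913
5	2.7278	2.4595
6	2.8497	2.5885
7	2.9483	2.6927
8	3.0309	2.7799
9	3.1017	2.8546
10	3.1637	2.9199
11	3.2187	2.9778
12	3.2680	3.0297
13	3.3127	3.0767
14	3.3536	3.1197
15	3.3912	3.1592
16	3.4260	3.1957
17	3.4584	3.2297
18	3.4887	3.2615
19	3.5171	3.2912
20	3.5438	3.3192
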
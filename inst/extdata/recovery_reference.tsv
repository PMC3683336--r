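# Reference edge-recovery counts from a chromosome-scale simulation
# benchmark: 10 replicate data sets (N = 4239) sampled from the serial
# skeleton model (p = 2863 SNPs, 2862 edges) and 10 from a fitted LD-graph
# model (4340 edges), each refitted with the fast forward-backward
# algorithm under BIC. Undershoot = true edges missed, overshoot = extra
# edges included.
# true_edges_skeleton: 2862
# true_edges_ldgraph: 4340
replicate	skeleton_undershoot	skeleton_overshoot	ldgraph_undershoot	ldgraph_overshoot
1	81	0	117	73
2	84	0	146	82
3	82	0	138	81
4	84	0	122	94
5	83	0	161	84
6	76	1	141	77
7	88	2	127	70
8	81	0	133	92
9	79	3	138	79
10	85	1	133	90
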
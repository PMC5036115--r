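id	5	6	7	8	9
X1	2.94244	1.00683	0.78548	0.67619	0.63273
X2	0.2987	0.43087	0.23714	0.16229	0.11456
X3	0.29665	1.71553	1.85274	1.79689	1.5142
X4	0.29848	1.08189	1.40472	1.72997	1.93474
X5	0.29922	0.91388	1.36444	1.53957	1.6857
X6	0.288	1.17602	1.93796	2.70139	3.37974
X7	0.30661	0.3989	0.78459	1.1844	2.27986
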
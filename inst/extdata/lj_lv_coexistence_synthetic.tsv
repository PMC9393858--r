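T	P
0.580	1.704493e-04
0.585	1.888354e-04
0.590	2.088417e-04
0.595	2.305771e-04
0.600	2.541549e-04
0.605	2.796932e-04
0.610	3.073149e-04
0.615	3.371477e-04
0.620	3.693243e-04
0.625	4.039821e-04
0.630	4.412635e-04
0.635	4.813160e-04
0.640	5.242916e-04
0.645	5.703477e-04
0.650	6.196464e-04
0.655	6.723548e-04
0.660	7.286448e-04
0.665	7.886933e-04
0.670	8.526820e-04
0.675	9.207975e-04
0.680	9.932312e-04
0.685	1.070179e-03
0.690	1.151842e-03
0.695	1.238426e-03
0.700	1.330140e-03
0.705	1.427199e-03
0.710	1.529821e-03
0.715	1.638232e-03
0.720	1.752657e-03
0.725	1.873330e-03
0.730	2.000485e-03
0.735	2.134363e-03
0.740	2.275208e-03
0.745	2.423268e-03
0.750	2.578794e-03
0.755	2.742042e-03
0.760	2.913270e-03
0.765	3.092741e-03
0.770	3.280721e-03
0.775	3.477477e-03
0.780	3.683281e-03
0.785	3.898410e-03
0.790	4.123139e-03
0.795	4.357750e-03
0.800	4.602526e-03
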
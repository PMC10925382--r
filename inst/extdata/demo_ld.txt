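1 0.3 0.09 0.027 0.0081 0.00243 0.000729 0.000219 6.6e-05 2e-05 6e-06 2e-06
0.3 1 0.3 0.09 0.027 0.0081 0.00243 0.000729 0.000219 6.6e-05 2e-05 6e-06
0.09 0.3 1 0.3 0.09 0.027 0.0081 0.00243 0.000729 0.000219 6.6e-05 2e-05
0.027 0.09 0.3 1 0.3 0.09 0.027 0.0081 0.00243 0.000729 0.000219 6.6e-05
0.0081 0.027 0.09 0.3 1 0.3 0.09 0.027 0.0081 0.00243 0.000729 0.000219
0.00243 0.0081 0.027 0.09 0.3 1 0.3 0.09 0.027 0.0081 0.00243 0.000729
0.000729 0.00243 0.0081 0.027 0.09 0.3 1 0.3 0.09 0.027 0.0081 0.00243
0.000219 0.000729 0.00243 0.0081 0.027 0.09 0.3 1 0.3 0.09 0.027 0.0081
6.6e-05 0.000219 0.000729 0.00243 0.0081 0.027 0.09 0.3 1 0.3 0.09 0.027
2e-05 6.6e-05 0.000219 0.000729 0.00243 0.0081 0.027 0.09 0.3 1 0.3 0.09
6e-06 2e-05 6.6e-05 0.000219 0.000729 0.00243 0.0081 0.027 0.09 0.3 1 0.3
2e-06 6e-06 2e-05 6.6e-05 0.000219 0.000729 0.00243 0.0081 0.027 0.09 0.3 1
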
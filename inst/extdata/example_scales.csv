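scale_id,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
KYTEDOOLITTLE,1.8,-4.5,-3.5,-3.5,2.5,-3.5,-3.5,-0.4,-3.2,4.5,3.8,-3.9,1.9,2.8,-1.6,-0.8,-0.7,-0.9,-1.3,4.2
HOPPWOODS,-0.5,3.0,0.2,3.0,-1.0,0.2,3.0,0.0,-0.5,-1.8,-1.8,3.0,-1.3,-2.5,0.0,0.3,-0.4,-3.4,-2.3,-1.5
EISENBERG,0.62,-2.53,-0.78,-0.90,0.29,-0.85,-0.74,0.48,-0.40,1.38,1.06,-1.50,0.64,1.19,0.12,-0.18,-0.05,0.81,0.26,1.08
FAUCHEREPLISKA,0.31,-1.01,-0.60,-0.77,1.54,-0.22,-0.64,0.00,0.13,1.80,1.70,-0.99,1.23,1.79,0.72,-0.04,0.26,2.25,0.96,1.22
JANIN,0.3,-1.4,-0.5,-0.6,0.9,-0.7,-0.7,0.3,-0.1,0.7,0.5,-1.8,0.4,0.5,-0.3,-0.1,-0.2,0.3,-0.4,0.6
ENGELMANGES,1.6,-12.3,-4.8,-9.2,2.0,-4.1,-8.2,1.0,-3.0,3.1,2.8,-8.8,3.4,3.7,-0.2,0.6,1.2,1.9,-0.7,2.6
ROSE,0.74,0.64,0.63,0.62,0.91,0.62,0.62,0.72,0.78,0.88,0.85,0.52,0.85,0.88,0.64,0.66,0.70,0.85,0.76,0.86
BLACKMOULD,0.616,0.000,0.236,0.028,0.680,0.251,0.043,0.501,0.165,0.943,0.943,0.283,0.738,1.000,0.711,0.359,0.450,0.878,0.880,0.825
WIMLEYWHITEIF,0.17,0.81,0.42,1.23,-0.24,0.58,2.02,0.01,0.96,-0.31,-0.56,0.99,-0.23,-1.13,0.45,0.13,0.14,-1.85,-0.94,0.07
MIYAZAWAJERNIGAN,5.33,4.18,3.71,3.59,7.93,3.87,3.65,4.48,5.10,8.83,8.47,2.95,8.95,9.03,3.87,4.09,4.49,7.66,5.89,7.63
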
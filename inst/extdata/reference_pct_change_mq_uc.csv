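material,analyte,level,d1,d2,d3,d4,d5,d6,d7,d8,d9,d10,d11,d12,d13,d14,d15,tcl
MQ,ALB,low,0,-0.92,0,-0.93,0,-2.78,-1.85,-0.93,-0.93,-0.93,0,0,-1.85,-1.85,0.926,3.43
MQ,ALB,high,-1.48,0.74,0,0,0,0,0,0,0,0,0,0,0,-0.74,0,3.43
MQ,ALP,low,0,0.505,1.515,1.515,2.778,3.283,3.283,3.03,5.051*,3.788,5.545*,4.293,3.788,3.788,3.788,4.66
MQ,ALP,high,0,-0.50,2.649,3.657,4.035,5.045,4.54,4.666*,5.423*,4.54,4.666*,4.666*,4.666*,3.909,4.414,4.66
MQ,ALT,low,1.118,1.616,3.715,0.808,-3.13,1.207,-2.32,0.853,0.519,-1.31,-2,-0.89,-5.48,-4.06,-4.42,5.64
MQ,ALT,high,-0.48,-1.13,-1.45,-2.42,-1.45,-2.26,-2.42,-3.06,-2.90,-2.90,-4.35,-2.90,-6.46*,-3.71,-5.00,5.64
MQ,Amylas,low,0.002,0.509,0.256,0.002,-0.25,,-0.51,0.002,-0.25,-0.25,-0.51,0.254,-1.27,0.003,0.254,3.83
MQ,Amylas,high,0.72,1.082,0.841,0.36,0.602,,-0.72,0.48,0.481,0.481,0.121,0.962,-0.48,-0.60,0.602,3.83
MQ,AST,low,0,-0.39,-1.58,-1.97,-1.58,-1.98,-2.76,-3.95,-5.14,-7.11*,-10.7*,-9.49*,-13.8*,-19.4*,19.76*,6.12
MQ,AST,high,0,0.129,0.124,-0.51,0.383,0.382,-0.13,-2.41,-2.67,-4.57,-6.73*,-6.10,-8.38*,-11.0*,-11.7*,6.12
MQ,Ca,low,0,-0.324,-0.327,0.647,-0.324,0.003,-1.951,-0.32,-1.631,-0.977,-2.278,-2.278,3.252,3.578,3.252,4.03
MQ,Ca,high,0,0.741,-1.23,1.478,0.494,1.725,0.247,1.724,1.232,0.494,-0.49,-0.00,8.378*,9.362*,8.129*,4.03
MQ,TChol,low,0,-0.17,0.355,0.355,0.176,1.417,1.77,1.063,1.418,1.062,0.531,1.417,-2.12,-1.42,-0.53,3.41
MQ,TChol,high,0,0.122,0.363,0.363,0.726,2.054,2.054,1.087,1.088,1.571,0.967,1.571,-1.69,-0.60,-0.36,3.41
MQ,CK,low,0.619,0.62,-0.25,-0.49,0.124,-1.11,-1.85,-1.47,-0.86,-1.48,-2.59,-1.48,-3.82,-2.34,-1.85,8.1
MQ,CK,high,-1.13,-0.15,-0.71,-1.23,-0.92,-1.54,-2.00,-2.46,-2.67,-2.47,-2.98,-2.62,-4.11,-3.49,-2.93,8.1
MQ,CL,low,-0.33,-0.03,-0.2,-1.40,-0.53,-0.4,-0.07,-0.13,0.067,-1.13,-0.3,-0.3,-1.00,-0.4,-0.03,2.27
MQ,CL,high,1.137,0.287,0.002,0,-0.28,-0.28,-0.28,-0.28,-0.56,0.002,-0.56,-0.57,-0.85,-1.13,-1.13,2.27
MQ,Crea,low,0.172,-0.17,-1.03,-0.86,0.172,,-1.20,-0.86,-1.72,-1.55,0.696,-0.68,-3.1,-1.20,0.005,4.4
MQ,Crea,high,0.261,0.52,0.983,0.056,,,-0.76,-0.40,-0.61,0.312,-0.30,-0.20,-1.39,-1.29,-0.15,4.4
MQ,cHDL,low,0,-2.70,-2.70,-2.70,-0.90,0,0,-2.70,-1.80,-3.60,-5.40,-5.40,-5.40,-5.40,-5.40,5.89
MQ,cHDL,high,0,-1.74,-2.32,-3.49,-0.57,0.585,0.01,-2.32,-2.89,-5.81,-5.81,-5.81,-3.48,-4.64,-4.06,5.89
MQ,DBil,low,2.381,7.143,7.143,7.143,7.143,7.143,7.143,7.143,0,-2.38,-2.38,-7.14,-7.14,-7.14,-9.52,19.01
MQ,DBil,high,0,3.846,3.846,3.846,6.41,5.128,1.282,3.846,0,-1.282,0,-1.282,-3.846,-3.846,-3.846,19.01
MQ,cLDL,low,0.273,0.817,-0.54,0,-0.27,0.815,0.546,0.273,-0.27,0.544,0.549,0.817,0.544,0.546,-0.27,4.98
MQ,cLDL,high,2.536,2.929,1.561,1.367,0.002,0.197,0.978,0.585,0.587,0.976,1.369,1.757,2.345,0.975,1.362,4.98
MQ,GGT,low,3.35,2.142,4.194,3.82,2.136,3.408,2.564,2.147,1.72,3.397,3.381,3.82,2.116,0.87,2.537,6.39
MQ,GGT,high,0.769,0.509,1.793,1.308,1.811,1.799,2.32,0.521,1.29,1.29,2.308,2.326,-0.006,3.083,2.829,6.39
MQ,Glu,low,0,0,1.488,1.488,1.786,2.083,1.786,0.893,1.19,1.19,1.786,1.786,-1.786,-0.893,-1.19,3.09
MQ,Glu,high,0,-0.199,1.397,1.994,2.293,2.892,2.592,1.794,1.695,1.595,1.795,2.093,-1.695,-1.196,-0.797,3.09
MQ,IP,low,0,0.813,0.813,-0.813,0.813,1.626,0,0,0.813,0.813,1.626,2.439,2.439,2.439,0,4.72
MQ,IP,high,-0.457,0.913,0.457,1.37,1.826,1.37,1.37,0.913,0.457,1.37,0.913,0.913,0.913,0.457,0.913,4.72
MQ,Iron,low,0.218,0.218,0.437,0.003,0.436,0.437,0.219,1.525,1.089,1.303,2.391,0.652,-0.22,0.654,0.87,13.35
MQ,Iron,high,1.326,1.62,1.327,1.033,0.593,0.885,0.737,1.177,1.324,1.177,1.031,1.32,0.595,0.737,1.624,13.35
MQ,K,low,0.44,0.177,0.438,0.613,0.525,0.264,-0.60,0.003,-0.34,0.267,-0.08,0.003,-0.52,0.612,0.959,2.37
MQ,K,high,0.228,0.773,0.183,0.545,0.864,0.546,0.091,0.273,-0.50,-0.23,0.272,0.091,-0.54,-0.14,0.228,2.37
MQ,LDH,low,0.56,-0.56,-0.18,-1.12,-3.54,-3.54,-2.80,-2.99,-2.98,-4.10,-3.73,-4.48,-6.16*,-4.48,-4.66*,4.55
MQ,LDH,high,1.285,1.045,1.205,0.161,0.241,-0.80,-0.64,0.402,-0.08,-1.12,-0.56,-0.80,-1.05,-0.40,-0.40,4.55
MQ,Mg,low,0,0,0,0,0,0,0,0,-4,0,1.333,0,-4,-1.33,0,5.71
MQ,Mg,high,-1.55,-0.74,0.038,-0.77,-1.55,-1.55,-2.36,0.038,-1.55,-0.74,-0.77,-1.55,-1.55,-0.74,-1.55,5.71
MQ,Na,low,0.243,0.24,0.48,0.48,0.243,0.003,-0.47,-0.23,-0.47,0.247,0.007,-0.23,-0.47,0.48,0.713,0.92
MQ,Na,high,0.214,0.214,0.001,-0.64,0.214,-0.21,-0.42,0,-0.42,-0.42,-0.21,0.001,-0.64,0,0.214,0.92
MQ,TBil,low,0,-1.01,0,-2.02,-3.03,-3.03,-2.02,-3.03,-3.03,-6.06,-9.09,-7.07,-15.1*,-15.1*,-18.2*,11.27
MQ,TBil,high,0,-1.30,-2.17,-2.17,-3.04,-2.17,-3.47,-4.78,-5.65,-6.08,-8.69,-8.69,-9.99,-10.9,-11.3*,11.27
MQ,TP,low,0,-0.62,-0.62,0,0,0,-1.23,-1.23,-1.85,-1.23,-1.85,0,-0.62,0,1.235,3.73
MQ,TP,high,0.966,0,-0.48,0,0,0,-0.97,-0.48,-1.45,0,0,0,0.483,0.966,0.966,3.73
MQ,Trig,low,0.939,0.941,1.413,1.648,2.118,2.59,2.589,2.354,3.06,4.94,4.237,3.766,4.237,5.411,5.412,10.37
MQ,Trig,high,1.225,1.684,2.725,2.75,3.055,3.212,2.75,2.598,3.981,3.362,3.666,3.667,3.513,3.975,5.04,10.37
MQ,UA,low,-1.12,-0.56,-0.56,-1.11,-0.56,-0.56,-0.56,-0.56,-0.56,-0.56,-0.56,0.565,-0.56,1.13,1.13,4.55
MQ,UA,high,0.721,0.362,1.079,0.362,0.362,0.725,0,0.725,0.362,0.004,0.362,1.083,1.441,1.083,1.8,4.55
MQ,UN,low,-0.79,-0.79,-2.4,-3.21,-3.21,-2.42,0,0.813,0.813,0.019,-0.79,0.019,-0.79,-0.79,-1.59,7.49
MQ,UN,high,0,-1.43,-2.86,-3.33,-3.33,-4.76,0.476,0,0,0,-1.43,0,-1.43,-2.86,-2.86,7.49
UC,Ca,low,-0.96,0,1.442,0,1.919,1.449,-1.43,0.483,-1.91,2.871,1.925,-0.48,2.374,-2.88,4.79,15.75
UC,Ca,high,0.002,-0.28,0.572,0,1.714,0.855,-1.14,0.287,0.575,6.572,6.86,6.278,2.289,-2.57,2.574,15.75
UC,CL,low,-0.99,-0.93,-1.96,-0.90,-0.43,0.402,-1.16,-1.76*,-1.66*,-1.20,-1.83*,-1.29,-1.46,-1.46,0.802,1.6
UC,CL,high,-0.52,-1.75,-1.23,-0.35,0.182,0,-0.52,-1.41,0.356,2.116*,2.996*,1.943*,1.588,3.964*,2.292*,1.6
UC,Crea,low,1.925,2.129,3.291,0.618,1.784,2.145,0.432,1.539,-1.01,-0.77,0.923,2.256,0.62,0.685,1.686,12.46
UC,Crea,high,0.954,1.464,2.404,0.686,1.47,2.837,0.04,1.565,-0.02,2.267,4.065,5.399,4.372,-0.272,2.004,12.46
UC,Glu,low,0,0,0,0,0,0,0,-3.33*,-5.56*,-3.33*,-3.33*,-3.33*,-3.33*,-4.44*,0,3
UC,Glu,high,0,0,0.69,0.461,0.231,0.692,0.116,-1.50,0.691,2.992,2.763,2.532,2.186,-1.04,0.575,3
UC,IP,low,0.749,0.739,3.591,4.439,4.817,4.851,4.32,1.733,0.638,0.749,1.737,4.197,2.607,2.842,3.454,9.47
UC,IP,high,-0.24,-1.22,0.802,2.202,4.037,3.676,3.246,1.104,1.105,3.616,4.703,6.968,6.482,1.381,1.288,9.47
UC,K,low,1.021,-2.76,1.531,1.224,1.736,1.534,1.022,0.307,0.205,1.327,-1.53,0.92,0.918,-0.20,-0.41,12.25
UC,K,high,1.735,1.734,1.831,1.66,3.1,1.213,2.646,2.105,4.553,7.046,9.004,7.649,7.638,7.186,3.149,12.25
UC,Mg,low,-1.41,-1.17,0.954,0.876,4.212,2.667,-11.5,-2.61,-1.26,-1.70,-4.98,-3.61,-3.46,-1.56,0.799,20.19
UC,Mg,high,0.519,0.104,1.326,3.325,3.486,4.878,-9.31,0.226,1.972,4.063,4.065,4.904,3.972,-0.53,0.682,20.19
UC,Na,low,0.155,5.117,1.202,0.581,0.388,0.116,0.698,0.582,-0.35,0.97,4.11,0.931,0.776,0.505,1.435,14.4
UC,Na,high,0.19,0.379,0.001,0.378,0.754,0.568,0.758,0.564,1.89,4.343,5.661,4.529,4.342,1.135,0.754,14.4
UC,UA,low,2.836,1.578,3.148,1.572,0.629,0.952,3.774,1.893,0.326,1.261,-0.31,0.003,-0.48,1.258,2.213,10.48
UC,UA,high,1.852,1.092,2.156,0.777,1.081,2.326,1.7,2.156,1.7,4.156,3.692,4.152,4.002,1.852,1.386,10.48
UC,microALB,low,0,-1.08,-1.48,0.882,-10.7,-12.1,-10.5,,-7.15,-1.37,-14.0,-12.8,-1.37,-6.85,4.107,22.23
UC,microALB,high,0,0.004,-1.14,-0.38,-1.90,-2.29,-3.83,-2.67,-4.98,-1.90,-3.05,-4.58,-20.7,,-20.7,22.23
UC,UN,low,2.668,2.322,5.753,2.293,1.576,4.603,-0.87,5.705,4.467,2.637,2.698,3.846,5.645,5.841,4.624,11.94
UC,UN,high,3.303,2.077,5.391,1.496,1.534,3.311,0.797,5.962,6.762,7.219,8.869,6.978,7.357,1.99,3.941,11.94
UC,TP,low,-1.65,2.855,2.748,1.981,3.653,-1.65,2.714,-0.55,0.428,2.913,2.339,2.493,2.082,4.251,3.526,19.6
UC,TP,high,-0.95,0.375,-0.74,-0.10,1.385,0.797,-0.21,0.267,1.647,3.396,3.079,3.604,2.334,-0.24,-1.37,19.6
UC,Amylas,low,-0.59,0.665,1.923,0.047,0.024,1.923,-0.62,0.665,-1.23,-2.52,-0.62,-1.23,-0.59,0.665,0.665,47.2
UC,Amylas,high,0.594,0.446,0.741,0.15,0.889,0,0.296,1.187,1.927,3.852,4.594,5.483,4.89,0.445,1.187,47.2
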
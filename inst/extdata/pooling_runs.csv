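pooling,run,sensitivity,specificity,precision,accuracy
SP,1,98.77,98.19,98.17,98.48
SP,2,98.47,97.58,97.57,98.02
SP,3,98.47,98.79,98.77,98.63
SP,4,98.16,98.79,98.77,98.48
SP,5,99.08,98.79,98.78,98.93
SP,6,98.77,98.79,98.77,98.78
SP,7,99.39,99.40,99.39,99.39
SP,8,99.08,98.49,98.48,98.78
SP,9,98.77,99.40,99.38,99.09
SP,10,98.77,99.40,99.38,99.09
MP,1,97.87,97.87,97.89,97.87
MP,2,98.63,98.63,98.66,98.63
MP,3,98.18,98.18,98.20,98.17
MP,4,96.04,96.04,96.11,96.04
MP,5,96.80,96.80,96.86,96.80
MP,6,98.78,98.78,98.81,98.78
MP,7,98.63,98.63,98.65,98.63
MP,8,97.86,97.86,97.88,97.87
MP,9,99.24,99.24,99.25,99.24
MP,10,98.63,98.63,98.64,98.63
AP,1,97.41,97.41,97.55,97.41
AP,2,96.65,96.66,96.67,96.65
AP,3,98.33,98.32,98.37,98.33
AP,4,97.41,97.41,97.42,97.41
AP,5,96.65,96.65,96.65,96.65
AP,6,97.87,97.87,97.88,97.87
AP,7,97.56,97.57,97.58,97.56
AP,8,97.87,97.87,97.92,97.87
AP,9,98.48,98.48,98.52,98.48
AP,10,98.48,98.47,98.51,98.48
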
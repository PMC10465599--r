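split,set,class,accuracy,precision,recall,specificity,f_score,mcc
80,train,1,97.34,92.67,92.77,98.36,92.72,91.09
80,train,2,96.74,90.24,91.11,97.93,90.67,88.70
80,train,3,97.45,89.25,94.44,97.98,91.77,90.31
80,train,4,96.46,90.17,86.22,98.30,88.15,86.10
80,train,5,97.08,92.46,90.75,98.42,91.59,89.83
80,train,6,97.86,93.71,93.32,98.76,93.51,92.23
80,test,1,97.40,91.46,92.36,98.36,91.91,90.37
80,test,2,96.57,91.61,90.29,98.05,90.95,88.84
80,test,3,97.20,89.88,92.39,98.09,91.11,89.47
80,test,4,96.69,89.34,86.83,98.31,88.07,86.16
80,test,5,97.01,90.66,91.92,98.05,91.28,89.48
80,test,6,97.48,93.51,92.70,98.55,93.10,91.56
70,train,1,97.26,92.11,92.57,98.27,92.34,90.67
70,train,2,98.09,94.91,94.05,98.94,94.48,93.32
70,train,3,97.06,90.36,90.30,98.28,90.33,88.60
70,train,4,96.42,88.96,87.24,98.06,88.09,85.99
70,train,5,96.30,90.18,88.62,97.94,89.39,87.15
70,train,6,97.73,91.56,95.24,98.23,93.37,92.02
70,test,1,96.80,91.02,90.75,98.09,90.88,88.94
70,test,2,97.80,94.54,93.47,98.78,94.00,92.65
70,test,3,97.17,90.29,90.92,98.27,90.61,88.94
70,test,4,96.46,87.92,88.08,97.91,88.00,85.92
70,test,5,96.09,89.48,87.42,97.88,88.44,86.10
70,test,6,97.17,90.43,93.22,97.98,91.81,90.11
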
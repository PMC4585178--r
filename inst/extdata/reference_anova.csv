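source,ss,df,ms,f
Model,4.46E-03,9,4.95E-04,35.35
x1,1.72E-05,1,1.72E-05,1.23
x2,3.28E-03,1,3.28E-03,233.93
x3,5.46E-04,1,5.46E-04,38.93
x1:x2,5.15E-05,1,5.15E-05,3.68
x1:x3,2.57E-04,1,2.57E-04,18.31
x2:x3,8.52E-05,1,8.52E-05,6.08
x1^2,3.26E-07,1,3.26E-07,0.023
x2^2,2.23E-04,1,2.23E-04,15.91
x3^2,3.16E-06,1,3.16E-06,0.23
Residual,1.40E-04,10,1.40E-05,
Lack of fit,1.29E-04,5,2.57E-05,11.15
Pure error,1.15E-05,5,2.31E-06,
Cor total,4.60E-03,19,,
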
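label,biomass,protein,surface_tension,clear_zone,overall_weight
a,0.5,0.04,40,5,0.0837007518599861
b,0.5,0.2,40,5,0.0888388696677219
c,0.5,1.1,40,5,0.100943628761928
d,0.5,2.9,40,5,0.11610106344395
e,0.5,6.5,40,5,0.138487898070806
f,0.5,0.05,40,5,0.0841188481875185
g,0.5,0.07,40,5,0.084878175165352
h,0.5,0.1,40,5,0.0859198921427006
i,0.5,0.45,40,5,0.0934139629212416
j,0.5,3.8,40,5,0.123596909778796
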
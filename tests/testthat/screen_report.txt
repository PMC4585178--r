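AHP screen 'wide.csv'
 label biomass protein surface_tension clear_zone overall_weight
     a     0.5    0.04              40          5         0.0837
     b     0.5    0.20              40          5         0.0888
     c     0.5    1.10              40          5         0.1009
     d     0.5    2.90              40          5         0.1161
     e     0.5    6.50              40          5         0.1385
     f     0.5    0.05              40          5         0.0841
     g     0.5    0.07              40          5         0.0849
     h     0.5    0.10              40          5         0.0859
     i     0.5    0.45              40          5         0.0934
     j     0.5    3.80              40          5         0.1236

Per-criterion consistency:
       criterion lambda_max     ci   ri   cr acceptable
         biomass    10.0000 0.0000 1.49 0.00       TRUE
         protein    12.2802 0.2534 1.49 0.17      FALSE
 surface_tension    10.0000 0.0000 1.49 0.00       TRUE
      clear_zone    10.0000 0.0000 1.49 0.00       TRUE
Criteria matrix: Consistency report (n = 4): lambda_max = 4.0457, CI = 0.0152, RI = 0.9, CR = 0.0169 [acceptable, CR < 0.1]
Best alternative: e  [WARNING: some CR >= threshold]
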
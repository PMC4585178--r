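{"experiment":"wide.csv","best_label":"e","best_index":5,"overall":{"a":0.0837007518599861,"b":0.0888388696677219,"c":0.100943628761928,"d":0.11610106344395,"e":0.138487898070806,"f":0.0841188481875185,"g":0.084878175165352,"h":0.0859198921427006,"i":0.0934139629212416,"j":0.123596909778796},"consistent":false,"criteria_weights":{"biomass":0.0980306809886277,"protein":0.182455656138209,"surface_tension":0.285558533969066,"clear_zone":0.433955128904097}}
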
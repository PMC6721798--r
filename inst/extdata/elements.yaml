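# FTL 5'-UTR regulatory-element map (1-based inclusive coordinates)
par: [53, 76]          # eIF3 PAR-CLIP site
re3: [58, 90]          # eIF3 repressive element (3RE)
loop_positions: [15, 16, 17]   # IRP contacts in the IRE apical loop
bulge: 18              # characteristic C bulge
cap_distance:
  native: 32
  extended: 70
steric_threshold: 60
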
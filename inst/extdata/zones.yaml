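# Immune-synapse zone assignments. Editable curation layer: only the three
# zone anchors and the adhesion partners reported with them are assigned;
# every other panel marker is treated as "unknown".
cSMAC:
  - CD3E
pSMAC:
  - CD11a
  - CD54
  - CD2
dSMAC:
  - CD44
general: []
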
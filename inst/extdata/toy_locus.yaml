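locus:
  chrom: chrK
  start: 1000
  end: 33000
chrom_lengths:
  chrK: 36000
  chrL: 8000
  chrH: 8000
  chrS: 15000
baits:
- name: J1CE
  side: CE
  chrom: chrK
  dsb_coordinate: 30500
  bait_strand: '-'
  primer:
  - 30540
  - 30560
  region:
  - 30350
  - 30650
- name: J1SE
  side: SE
  chrom: chrK
  dsb_coordinate: 30499
  bait_strand: +
  primer:
  - 30440
  - 30460
  region:
  - 30350
  - 30650
stads:
- label: sTAD1-2
  start: 2000
  end: 9000
- label: sTAD3
  start: 9000
  end: 16000
- label: sTAD4
  start: 16000
  end: 23000
- label: sTAD5
  start: 23000
  end: 29500
receptor_loci:
- label: recL
  chrom: chrL
  start: 3000
  end: 3400
- label: recH
  chrom: chrH
  start: 3000
  end: 3400
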
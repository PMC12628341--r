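 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.0353868008397151E-01   1   1   1   1
  2.6429356607956217E-01   2   1   2   1
  5.1306069612009153E-01   2   2   1   1
  5.2706592620042869E-01   2   2   2   2
 -7.5985273987895030E-01   1   1   0   0
 -6.6789623022334987E-01   2   2   0   0
  2.5198914805714284E-01   0   0   0   0
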
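 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.7827697368394926E-01   1   1   1   1
  2.1641745962374648E-01   2   1   2   1
  5.8158673480234491E-01   2   2   1   1
  6.0874563847643881E-01   2   2   2   2
 -9.7922349123845409E-01   1   1   0   0
 -6.4824211771103979E-01   2   2   0   0
  4.0705939301538463E-01   0   0   0   0
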
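 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  6.4455265512659521E-01   1   1   1   1
  1.9057169375926430E-01   2   1   2   1
  6.3708062989503056E-01   2   2   1   1
  6.6948503793215852E-01   2   2   2   2
 -1.1622206874733227E+00   1   1   0   0
 -5.5511231982008458E-01   2   2   0   0
  5.8797467879999998E-01   0   0   0   0
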
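 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  6.8238953315204121E-01   1   1   1   1
  1.7900057606140629E-01   2   1   2   1
  6.7073277830875888E-01   2   2   1   1
  7.0510563217279154E-01   2   2   2   2
 -1.2778530061568700E+00   1   1   0   0
 -4.4829969610162379E-01   2   2   0   0
  7.5596744417142869E-01   0   0   0   0
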
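 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  6.0917167853723575E-01   1   1   1   1
  2.0322222662064948E-01   2   1   2   1
  6.0733542771978399E-01   2   2   1   1
  6.3747987715403509E-01   2   2   2   2
 -1.0633903726559351E+00   1   1   0   0
 -6.1475271767395212E-01   2   2   0   0
  4.8107019174545451E-01   0   0   0   0
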
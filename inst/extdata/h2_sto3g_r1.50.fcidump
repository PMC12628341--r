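 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.5270338306241384E-01   1   1   1   1
  2.2953593605970052E-01   2   1   2   1
  5.5968415561301343E-01   2   2   1   1
  5.8342076120372643E-01   2   2   2   2
 -9.0818087246840051E-01   1   1   0   0
 -6.6533693576482056E-01   2   2   0   0
  3.5278480728000000E-01   0   0   0   0
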
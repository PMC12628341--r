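 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.3224624838189027E-01   1   1   1   1
  2.4207283851911027E-01   2   1   2   1
  5.4128317435322348E-01   2   2   1   1
  5.6155238279019504E-01   2   2   2   2
 -8.4893229381953295E-01   1   1   0   0
 -6.7189618764434211E-01   2   2   0   0
  3.1128071230588239E-01   0   0   0   0
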
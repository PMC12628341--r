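 &FCI NORB=2,NELEC=2,MS2=0,
  ORBSYM=1,1,
  ISYM=1,
 &END
  5.1615143349097847E-01   1   1   1   1
  2.5371042781261460E-01   2   1   2   1
  5.2591080537821189E-01   2   2   1   1
  5.4290625260330760E-01   2   2   2   2
 -7.9999929996054431E-01   1   1   0   0
 -6.7188513248411574E-01   2   2   0   0
  2.7851432153684214E-01   0   0   0   0
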
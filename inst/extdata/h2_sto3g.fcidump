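&FCI NORB=2,NELEC=2,MS2=0,
 ORBSYM=1,1,
 ISYM=1,
&END
 0.6744931660000000e+00   1   1   1   1
 0.6634721010000000e+00   1   1   2   2
 0.1812875180000000e+00   1   2   1   2
 0.6973971500000000e+00   2   2   2   2
-0.1252477495000000e+01   1   1   0   0
-0.4759342750000000e+00   2   2   0   0
 0.7137538870000000e+00   0   0   0   0
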
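time_s,stage_um,cantilever_um
0,0.0274191689429334,-0.0391919470440188
0.1,0.488706036572078,0.153489966886436
0.2,1.00726256822675,0.183609145875593
0.3,1.51265725209922,0.236478900004429
0.4,2.00808536646282,0.331431959416942
0.5,2.49787750967817,0.443221216436197
0.6,3.03023043994878,0.512064936002149
0.7,3.49810681923174,0.463252629129192
0.8,4.04036847427754,0.739640660668986
0.9,4.49874571801895,0.826656667565668
1,5.02609739308447,0.980896533191156
1.1,5.54573290785402,1.1341228925543
1.2,5.97222278597775,1.31493333743619
1.3,6.49442422466365,1.3547273229378
1.4,6.99733357327213,1.60829796704474
1.5,7.5127190079614,1.71767958525458
1.6,7.99431494157168,1.9158784450616
1.7,8.4468708915819,2.07812994403716
1.8,8.95119066142849,2.24109206997459
1.9,9.5264022669146,2.33041714437331
2,9.99386722811843,2.55993134900082
2.1,9.9643738313204,2.54150794194956
2.2,9.99656165288481,2.41360509134018
2.3,10.0242934939835,2.389688933737
2.4,10.0379038692253,2.4056091751188
2.5,9.99139061736788,2.37849277398337
2.6,9.99485461234462,2.33024117701665
2.7,9.9647367382961,2.23285730228319
2.8,10.0092019470966,2.19508320695242
2.9,9.9872001024808,2.3012013109219
3,10.0091090024648,2.21628221647172
3.1,10.0140967467446,2.18773582488378
3.2,10.0207020704394,2.15910535228373
3.3,9.98782147249186,2.08899844208545
3.4,10.010099102466,2.16444422191145
3.5,9.96565982641853,2.10953338448121
3.6,9.98431081983241,2.09908067820292
3.7,9.98298184811647,2.14387436102772
3.8,9.95171584700107,2.12833435096046
3.9,10.0007224521378,2.14784041777266
4,10.004119972004,2.04627463262449
4.1,9.99277885402903,2.09522744655171
4.2,10.015163264714,2.12559608383786
4.3,9.98546590345847,1.99446843624472
4.4,9.97263437911161,2.00151164049357
4.5,10.0086563605178,1.98302885902198
4.6,9.98377213647627,1.96219103785468
4.7,10.0288820252344,2.03511325043554
4.8,9.99137107594773,2.06012246631678
4.9,10.013112957668,2.08420756456157
5,10.0064385053041,2.07340950381849
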
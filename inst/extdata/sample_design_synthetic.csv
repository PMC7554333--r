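Plot,Barcode,Range,Row
1,CS17-G2FE-001,1,1
1,CS17-G2FE-001,1,2
1,CS17-G2FE-001,1,3
1,CS17-G2FE-001,1,4
1,CS17-G2FE-001,1,5
1,CS17-G2FE-001,1,6
2,CS17-G2FE-002,1,7
2,CS17-G2FE-002,1,8
2,CS17-G2FE-002,1,9
2,CS17-G2FE-002,1,10
2,CS17-G2FE-002,1,11
2,CS17-G2FE-002,1,12
3,CS17-G2FE-003,2,1
3,CS17-G2FE-003,2,2
3,CS17-G2FE-003,2,3
3,CS17-G2FE-003,2,4
3,CS17-G2FE-003,2,5
3,CS17-G2FE-003,2,6
4,CS17-G2FE-004,2,7
4,CS17-G2FE-004,2,8
4,CS17-G2FE-004,2,9
4,CS17-G2FE-004,2,10
4,CS17-G2FE-004,2,11
4,CS17-G2FE-004,2,12
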
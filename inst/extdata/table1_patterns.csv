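cytology,DHPLC,DBH,RFLP1,RFLP2,count
1,1,1,1,NA,1
1,1,1,1,1,254
1,1,1,1,2,43
1,1,1,2,1,3
1,1,1,2,3,7
1,1,2,2,2,2
1,1,2,3,3,3
1,1,3,1,2,1
1,1,3,2,2,3
1,1,3,3,1,1
1,1,3,3,3,3
1,2,1,1,1,3
1,2,1,2,2,5
1,2,1,3,2,1
1,2,2,1,1,5
1,2,2,1,2,2
1,2,2,1,3,7
1,2,2,2,2,349
1,2,2,2,3,2
1,2,3,1,1,1
1,2,3,2,2,4
1,2,3,3,3,4
1,3,1,1,1,1
1,3,1,2,2,1
1,3,1,3,1,1
1,3,2,1,1,2
1,3,2,2,2,1
1,3,2,2,3,1
1,3,3,1,3,2
1,3,3,2,3,12
1,3,3,3,3,125
2,1,1,1,1,28
2,1,1,1,2,1
2,1,1,1,3,1
2,1,1,2,1,1
2,1,3,3,3,1
2,2,1,1,2,1
2,2,2,2,2,21
2,2,3,3,3,1
2,3,3,2,3,1
2,3,3,3,3,5
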
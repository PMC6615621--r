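sex,group,outcome,a0,a1,a2
1,Caucasian,FVC,-9.785,2.2,0.03
1,Caucasian,FEV1,-10.0081,2.2,0.03
1,AfricanAmerican,FVC,-9.905,2.2,0.03
1,AfricanAmerican,FEV1,-10.1281,2.2,0.03
1,NorthEastAsian,FVC,-9.835,2.2,0.03
1,NorthEastAsian,FEV1,-10.0581,2.2,0.03
1,SouthEastAsian,FVC,-9.885,2.2,0.03
1,SouthEastAsian,FEV1,-10.1081,2.2,0.03
1,Other,FVC,-9.845,2.2,0.03
1,Other,FEV1,-10.0681,2.2,0.03
2,Caucasian,FVC,-9.987,2.2,0.03
2,Caucasian,FEV1,-10.2101,2.2,0.03
2,AfricanAmerican,FVC,-10.107,2.2,0.03
2,AfricanAmerican,FEV1,-10.3301,2.2,0.03
2,NorthEastAsian,FVC,-10.037,2.2,0.03
2,NorthEastAsian,FEV1,-10.2601,2.2,0.03
2,SouthEastAsian,FVC,-10.087,2.2,0.03
2,SouthEastAsian,FEV1,-10.3101,2.2,0.03
2,Other,FVC,-10.047,2.2,0.03
2,Other,FEV1,-10.2701,2.2,0.03
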
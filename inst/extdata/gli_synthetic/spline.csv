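sex,group,outcome,age,spline_value
1,Caucasian,FVC,4,-0.25
1,Caucasian,FVC,10,-0.12
1,Caucasian,FVC,18,0
1,Caucasian,FVC,30,0
1,Caucasian,FVC,45,-0.05
1,Caucasian,FVC,60,-0.15
1,Caucasian,FVC,80,-0.3
1,Caucasian,FVC,90,-0.35
1,Caucasian,FEV1,4,-0.25
1,Caucasian,FEV1,10,-0.12
1,Caucasian,FEV1,18,0
1,Caucasian,FEV1,30,0
1,Caucasian,FEV1,45,-0.05
1,Caucasian,FEV1,60,-0.15
1,Caucasian,FEV1,80,-0.3
1,Caucasian,FEV1,90,-0.35
1,AfricanAmerican,FVC,4,-0.25
1,AfricanAmerican,FVC,10,-0.12
1,AfricanAmerican,FVC,18,0
1,AfricanAmerican,FVC,30,0
1,AfricanAmerican,FVC,45,-0.05
1,AfricanAmerican,FVC,60,-0.15
1,AfricanAmerican,FVC,80,-0.3
1,AfricanAmerican,FVC,90,-0.35
1,AfricanAmerican,FEV1,4,-0.25
1,AfricanAmerican,FEV1,10,-0.12
1,AfricanAmerican,FEV1,18,0
1,AfricanAmerican,FEV1,30,0
1,AfricanAmerican,FEV1,45,-0.05
1,AfricanAmerican,FEV1,60,-0.15
1,AfricanAmerican,FEV1,80,-0.3
1,AfricanAmerican,FEV1,90,-0.35
1,NorthEastAsian,FVC,4,-0.25
1,NorthEastAsian,FVC,10,-0.12
1,NorthEastAsian,FVC,18,0
1,NorthEastAsian,FVC,30,0
1,NorthEastAsian,FVC,45,-0.05
1,NorthEastAsian,FVC,60,-0.15
1,NorthEastAsian,FVC,80,-0.3
1,NorthEastAsian,FVC,90,-0.35
1,NorthEastAsian,FEV1,4,-0.25
1,NorthEastAsian,FEV1,10,-0.12
1,NorthEastAsian,FEV1,18,0
1,NorthEastAsian,FEV1,30,0
1,NorthEastAsian,FEV1,45,-0.05
1,NorthEastAsian,FEV1,60,-0.15
1,NorthEastAsian,FEV1,80,-0.3
1,NorthEastAsian,FEV1,90,-0.35
1,SouthEastAsian,FVC,4,-0.25
1,SouthEastAsian,FVC,10,-0.12
1,SouthEastAsian,FVC,18,0
1,SouthEastAsian,FVC,30,0
1,SouthEastAsian,FVC,45,-0.05
1,SouthEastAsian,FVC,60,-0.15
1,SouthEastAsian,FVC,80,-0.3
1,SouthEastAsian,FVC,90,-0.35
1,SouthEastAsian,FEV1,4,-0.25
1,SouthEastAsian,FEV1,10,-0.12
1,SouthEastAsian,FEV1,18,0
1,SouthEastAsian,FEV1,30,0
1,SouthEastAsian,FEV1,45,-0.05
1,SouthEastAsian,FEV1,60,-0.15
1,SouthEastAsian,FEV1,80,-0.3
1,SouthEastAsian,FEV1,90,-0.35
1,Other,FVC,4,-0.25
1,Other,FVC,10,-0.12
1,Other,FVC,18,0
1,Other,FVC,30,0
1,Other,FVC,45,-0.05
1,Other,FVC,60,-0.15
1,Other,FVC,80,-0.3
1,Other,FVC,90,-0.35
1,Other,FEV1,4,-0.25
1,Other,FEV1,10,-0.12
1,Other,FEV1,18,0
1,Other,FEV1,30,0
1,Other,FEV1,45,-0.05
1,Other,FEV1,60,-0.15
1,Other,FEV1,80,-0.3
1,Other,FEV1,90,-0.35
2,Caucasian,FVC,4,-0.25
2,Caucasian,FVC,10,-0.12
2,Caucasian,FVC,18,0
2,Caucasian,FVC,30,0
2,Caucasian,FVC,45,-0.05
2,Caucasian,FVC,60,-0.15
2,Caucasian,FVC,80,-0.3
2,Caucasian,FVC,90,-0.35
2,Caucasian,FEV1,4,-0.25
2,Caucasian,FEV1,10,-0.12
2,Caucasian,FEV1,18,0
2,Caucasian,FEV1,30,0
2,Caucasian,FEV1,45,-0.05
2,Caucasian,FEV1,60,-0.15
2,Caucasian,FEV1,80,-0.3
2,Caucasian,FEV1,90,-0.35
2,AfricanAmerican,FVC,4,-0.25
2,AfricanAmerican,FVC,10,-0.12
2,AfricanAmerican,FVC,18,0
2,AfricanAmerican,FVC,30,0
2,AfricanAmerican,FVC,45,-0.05
2,AfricanAmerican,FVC,60,-0.15
2,AfricanAmerican,FVC,80,-0.3
2,AfricanAmerican,FVC,90,-0.35
2,AfricanAmerican,FEV1,4,-0.25
2,AfricanAmerican,FEV1,10,-0.12
2,AfricanAmerican,FEV1,18,0
2,AfricanAmerican,FEV1,30,0
2,AfricanAmerican,FEV1,45,-0.05
2,AfricanAmerican,FEV1,60,-0.15
2,AfricanAmerican,FEV1,80,-0.3
2,AfricanAmerican,FEV1,90,-0.35
2,NorthEastAsian,FVC,4,-0.25
2,NorthEastAsian,FVC,10,-0.12
2,NorthEastAsian,FVC,18,0
2,NorthEastAsian,FVC,30,0
2,NorthEastAsian,FVC,45,-0.05
2,NorthEastAsian,FVC,60,-0.15
2,NorthEastAsian,FVC,80,-0.3
2,NorthEastAsian,FVC,90,-0.35
2,NorthEastAsian,FEV1,4,-0.25
2,NorthEastAsian,FEV1,10,-0.12
2,NorthEastAsian,FEV1,18,0
2,NorthEastAsian,FEV1,30,0
2,NorthEastAsian,FEV1,45,-0.05
2,NorthEastAsian,FEV1,60,-0.15
2,NorthEastAsian,FEV1,80,-0.3
2,NorthEastAsian,FEV1,90,-0.35
2,SouthEastAsian,FVC,4,-0.25
2,SouthEastAsian,FVC,10,-0.12
2,SouthEastAsian,FVC,18,0
2,SouthEastAsian,FVC,30,0
2,SouthEastAsian,FVC,45,-0.05
2,SouthEastAsian,FVC,60,-0.15
2,SouthEastAsian,FVC,80,-0.3
2,SouthEastAsian,FVC,90,-0.35
2,SouthEastAsian,FEV1,4,-0.25
2,SouthEastAsian,FEV1,10,-0.12
2,SouthEastAsian,FEV1,18,0
2,SouthEastAsian,FEV1,30,0
2,SouthEastAsian,FEV1,45,-0.05
2,SouthEastAsian,FEV1,60,-0.15
2,SouthEastAsian,FEV1,80,-0.3
2,SouthEastAsian,FEV1,90,-0.35
2,Other,FVC,4,-0.25
2,Other,FVC,10,-0.12
2,Other,FVC,18,0
2,Other,FVC,30,0
2,Other,FVC,45,-0.05
2,Other,FVC,60,-0.15
2,Other,FVC,80,-0.3
2,Other,FVC,90,-0.35
2,Other,FEV1,4,-0.25
2,Other,FEV1,10,-0.12
2,Other,FEV1,18,0
2,Other,FEV1,30,0
2,Other,FEV1,45,-0.05
2,Other,FEV1,60,-0.15
2,Other,FEV1,80,-0.3
2,Other,FEV1,90,-0.35
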
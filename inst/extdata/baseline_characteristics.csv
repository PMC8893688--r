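no,group,age,sex,lesion,hand_pre,hand_post,years_post_stroke,neadl,fm,anx,dep
1,1,80,M,unconf,right,right,>1,28,9,7,11
2,1,75,F,unconf,right,right,>2,49,5,9,4
3,1,67,F,unconf,right,left,>5,42,20,5,12
4,1,53,F,left,right,right,>2,45,10,1,3
5,1,72,M,right,right,right,>5,42,20,4,2
6,1,66,F,right,right,right,>10,33,20,11,9
7,1,56,M,left,right,left,>1,30,14,4,9
8,1,67,M,right,left,right,>10,49,3,10,10
9,2,67,M,left,left,left,>5,35,16,14,12
10,2,79,M,right,right,left,>2,10,4,6,9
11,2,68,M,right,right,left,>6,28,1,4,5
12,2,75,F,bilat,right,right,>1,38,1,2,1
13,2,67,F,right,right,right,>2,32,NA,4,0
14,2,77,M,unconf,right,left,>1,16,15,4,1
15,2,64,F,left,left,left,>5,48,2,6,11
16,2,69,F,right,right,right,>5,49,18,2,5
17,2,77,F,right,right,right,>2,51,12,10,5
18,2,65,F,bilat,right,right,>10,45,13,1,7
19,2,78,M,left,left,left,>10,24,15,3,2
20,2,82,M,unconf,right,right,>5,54,20,4,4
21,2,68,F,unconf,left,both,>10,40,13,7,4
22,2,79,M,left,right,right,>2,47,14,6,6
23,2,64,M,unconf,n/a,n/a,4,35,5,4,6
24,1,81,M,unconf,n/a,n/a,8,41,9,7,6
25,1,81,M,unconf,n/a,n/a,1,40,20,0,2
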
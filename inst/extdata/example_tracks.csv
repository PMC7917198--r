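track_id,frame,x,y
1,0,420,30
1,1,408,36
1,2,395,41
1,3,381,38
1,4,367,45
2,0,150,-60
2,1,139,-52
2,2,131,-47
2,3,120,-50
2,4,108,-44
3,0,95,110
3,1,101,118
3,2,94,125
3,3,88,117
3,4,95,112
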
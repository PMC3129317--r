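from_code,from_label,to_code,to_label,count
4,recessing,1,cementing,0
4,recessing,6,nestling,0
4,recessing,2,byssal,0
4,recessing,3,free-living,0
4,recessing,5,gliding,2
1,cementing,2,byssal,0
1,cementing,3,free-living,0
1,cementing,4,recessing,0
1,cementing,5,gliding,0
1,cementing,6,nestling,0
6,nestling,1,cementing,0
6,nestling,2,byssal,0
6,nestling,3,free-living,0
6,nestling,4,recessing,0
6,nestling,5,gliding,0
2,byssal,1,cementing,2
2,byssal,6,nestling,1
2,byssal,3,free-living,6
2,byssal,4,recessing,1
2,byssal,5,gliding,2
3,free-living,1,cementing,0
3,free-living,6,nestling,0
3,free-living,2,byssal,1
3,free-living,4,recessing,1
3,free-living,5,gliding,0
5,gliding,1,cementing,0
5,gliding,6,nestling,0
5,gliding,2,byssal,0
5,gliding,4,recessing,0
5,gliding,3,free-living,1
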
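inventory_increment,lidar_increment,n
-1,-2,1
-1,1,1
0,-2,1
0,-1,2
0,0,4
0,1,8
0,2,20
0,3,1
1,-5,1
1,-4,1
1,-3,2
1,-2,1
1,-1,2
1,0,1
1,1,9
1,2,35
1,3,6
2,0,3
2,1,7
2,2,31
2,3,29
2,4,6
3,2,2
3,3,18
3,4,11
3,5,3
4,2,2
4,3,5
4,4,2
8,5,1
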
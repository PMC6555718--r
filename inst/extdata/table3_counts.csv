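# Published correspondence counts: clinical stage (rows) x measured temperature bin (columns),
# for 305 hypothermia cases (122 hospital sampling, 183 literature review).
# bin 1: 32 <= T < 35; bin 2: 28 <= T < 32; bin 3: 24 <= T < 28; bin 4: T < 24.
stratum,stage,bin,count
hospital,1,1,66
hospital,1,2,13
hospital,1,3,0
hospital,1,4,0
hospital,2,1,4
hospital,2,2,15
hospital,2,3,3
hospital,2,4,1
hospital,3,1,1
hospital,3,2,5
hospital,3,3,4
hospital,3,4,2
hospital,4,1,0
hospital,4,2,1
hospital,4,3,2
hospital,4,4,5
literature,1,1,4
literature,1,2,6
literature,1,3,0
literature,1,4,0
literature,2,1,3
literature,2,2,11
literature,2,3,8
literature,2,4,2
literature,3,1,3
literature,3,2,12
literature,3,3,33
literature,3,4,20
literature,4,1,0
literature,4,2,9
literature,4,3,25
literature,4,4,47
overall,1,1,70
overall,1,2,19
overall,1,3,0
overall,1,4,0
overall,2,1,7
overall,2,2,26
overall,2,3,11
overall,2,4,3
overall,3,1,4
overall,3,2,17
overall,3,3,37
overall,3,4,22
overall,4,1,0
overall,4,2,10
overall,4,3,27
overall,4,4,52
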
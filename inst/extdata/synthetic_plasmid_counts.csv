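# seed: 2026
# transfer_interval: 24
# beta: 10000
# n: 100
# replicates: 3
# duration: 240
# initial_size: 10000
# initial_revertants: 0
# truncated: FALSE,FALSE,FALSE
replicate,time_h,n_sampled,x_engineered
r1,0,100,100
r1,24,100,88
r1,48,100,71
r1,72,100,60
r1,96,100,37
r1,120,100,29
r1,144,100,24
r1,168,100,12
r1,192,100,8
r1,216,100,5
r1,240,100,2
r2,0,100,100
r2,24,100,87
r2,48,100,66
r2,72,100,56
r2,96,100,44
r2,120,100,29
r2,144,100,21
r2,168,100,15
r2,192,100,12
r2,216,100,9
r2,240,100,4
r3,0,100,100
r3,24,100,86
r3,48,100,66
r3,72,100,58
r3,96,100,45
r3,120,100,23
r3,144,100,16
r3,168,100,12
r3,192,100,13
r3,216,100,5
r3,240,100,8
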
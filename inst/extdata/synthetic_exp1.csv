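# note: synthetic data sampled from the encoding-reset model (no human data)
# model: reset
# params: vp=0.06 vr=0.04 t0=15 s0=18 tau=0
# design: exp1
# seed: 42
participant,condition,soa_ms,n_trials,n_probe_first
S1,neutral,-100,240,239
S1,neutral,-90,240,238
S1,neutral,-80,240,240
S1,neutral,-70,240,237
S1,neutral,-60,240,236
S1,neutral,-50,240,233
S1,neutral,-40,240,222
S1,neutral,-30,240,210
S1,neutral,-20,240,184
S1,neutral,-10,240,148
S1,neutral,0,240,147
S1,neutral,10,240,124
S1,neutral,20,240,86
S1,neutral,30,240,71
S1,neutral,40,240,41
S1,neutral,50,240,27
S1,neutral,60,240,6
S1,neutral,70,240,6
S1,neutral,80,240,9
S1,neutral,90,240,4
S1,neutral,100,240,2
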
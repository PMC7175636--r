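{"model":"voter","t_max":1,"arrows":[[0.3,0,1],[0.7,1,2]],"recoveries":[]}
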
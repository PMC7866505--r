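units: cm
D12s: 114.0
D23s: 143.0139853
D34s: 114.0
D41s: 143.0139853
D13s: 184.133104
D24s: 181.6397534
Dg: 15.0
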
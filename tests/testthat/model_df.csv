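topology,observed,free,df
simplest,12,28,50
simple,12,28,50
complex,21,63,168
complex_path,10,46,9
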
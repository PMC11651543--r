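domain	start	end
I	1	198
II	199	327
III	328	532
IV	533	667
V	668	789
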
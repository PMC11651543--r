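name	start	end	binds
F4	246	399	0
F5	301	451	0
F6	352	500	1
F7	400	550	1
F8	502	651	1
F9	602	749	0
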
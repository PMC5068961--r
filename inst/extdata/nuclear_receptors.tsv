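tf_id	is_nuclear_receptor
Hr78	TRUE
Hr38	TRUE
Hr46	TRUE
Eip78C	TRUE
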
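raw	accepted
Ocotea javitensi	Ocotea javitensis
Virola surinamenses	Virola surinamensis
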
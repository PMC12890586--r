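plot_id	landscape_integrity
P001	91.5
P002	90.2
P003	76.4
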
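plot_id	region	lon	lat	elevation_m	area_ha	swamp	flooded	fire	large_disturbance	taxonomy_issue
P001	WA	-72.4	-4.1	160	1	FALSE	FALSE	FALSE	FALSE	FALSE
P002	WA	-72.38	-4.12	170	1	FALSE	FALSE	FALSE	FALSE	FALSE
P003	WA	-71.9	-3.8	140	1	FALSE	FALSE	FALSE	FALSE	FALSE
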
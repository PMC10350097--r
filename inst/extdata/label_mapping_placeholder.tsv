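# Placeholder (synthetic) tract label mapping.
# Real use: supply your atlas's merge table in this two-column format,
# mapping source label names to merged output channels (e.g. merging the
# left and right sections of bilateral tracts into one label each).
# source_label	merged_label
AF_left	AF
AF_right	AF
CC_genu	CC_genu
CST_left	CST
CST_right	CST
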
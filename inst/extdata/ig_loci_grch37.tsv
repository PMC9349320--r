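# Immunoglobulin locus exclusion intervals, GRCh37 (1-based inclusive).
# Default intervals; replace with your own file to override.
chrom	start	end	locus
14	106032614	107288051	IGH
2	89156874	90274235	IGK
22	22380474	23265085	IGL
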
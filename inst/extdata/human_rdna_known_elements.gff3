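##gff-version 3
# Previously characterized elements of the human rDNA repeat unit,
# on the 43,972 bp single-BAC-derived reference unit whose position 1 is
# the rRNA transcription start (coding region 1..13,357; IGS
# 13,358..43,972).
#
# Provenance of each record is given in its `note` attribute. Promoter
# control-element coordinates are mapped from their published positions
# relative to the transcription start (UCE -156..-107, CCE -45..+18); the
# CCE crosses the unit origin and is stored as two records. Terminator
# (Sal-box) sites are motif-defined (consensus GGGTCGACCAG) and should be
# located on an actual unit sequence with find_sal_boxes(); no fixed
# coordinates are shipped. Coordinates of the stress-induced IGS
# noncoding transcripts (IGS_21_RNA, IGS_28_RNA) are not reproduced in the
# literature consulted here and must be supplied by the user as a
# transcript track; they are known to coincide with conserved regions
# c20-c23 and c28-c30 respectively.
human_rDNA	known_elements	region	1	13357	.	+	.	ID=rRNA_coding;note=18S-5.8S-28S coding region incl. transcribed spacers
human_rDNA	known_elements	region	13358	43972	.	.	.	ID=IGS;note=intergenic spacer
human_rDNA	known_elements	regulatory_region	43817	43866	.	+	.	ID=UCE;note=upstream control element%2C published position -156..-107 relative to transcription start
human_rDNA	known_elements	regulatory_region	43928	43972	.	+	.	ID=CCE_upstream;note=core control element upstream half%2C published position -45..-1
human_rDNA	known_elements	regulatory_region	1	18	.	+	.	ID=CCE_downstream;note=core control element downstream half%2C published position +1..+18
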
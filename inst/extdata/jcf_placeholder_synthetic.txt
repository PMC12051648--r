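# Synthetic placeholder gene set for the juxta-cardiac-field (JCF) score.
# These are NOT the published JCF cluster markers: supply your own list
# (one gene per line) from the heart-atlas resource of your choice.
Mab21l2
Nkx2-5
Tbx5
Hand1
Bmp4
Wt1
Tcf21
Sfrp5
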
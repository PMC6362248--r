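# Synthetic SB-like demonstration model: a randomly generated 1638-nt
# element with Sleeping-Beauty-like geometry (227-nt inverted terminal
# repeats flanking a 1022-nt transposase CDS). This is NOT the real
# Sleeping Beauty construct; supply your own config to analyse one.
#
# Binding-region boxes are editable values (full-sequence 1-based closed
# coordinates); every binding-region-dependent report carries the spans
# actually used.
name: synthetic_sb_like
sequence_file: synthetic_sb_like.fasta
left_itr:
  start: 1
  end: 227
cds:
  start: 300
  end: 1321
  frame: 0
right_itr:
  start: 1412
  end: 1638
binding_regions:
  - itr: left_itr
    start: 3
    end: 28
  - itr: left_itr
    start: 196
    end: 225
  - itr: right_itr
    start: 1416
    end: 1441
  - itr: right_itr
    start: 1601
    end: 1631
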
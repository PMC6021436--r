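# Synthetic scaffold template stubs.
#
# These are NOT the published construct sequences (those are distributed
# only as supplementary material). They are structurally faithful
# stand-ins assembled from the canonical SpCas9 sgRNA backbone and the
# well-known MS2/PP7 aptamer motifs, preserving the relationships the
# variants are defined by:
#   - gRNA carries the tracr terminator hairpin and no aptamer;
#   - scRNA_original appends one MS2 hairpin 3' of the terminator;
#   - scRNA.b1 removes the terminator and keeps one 3' MS2 hairpin;
#   - scRNA.b2 differs from scRNA.b1 at exactly one base at the former
#     terminator junction;
#   - scRNA_2xMS2 carries two MS2 hairpins;
#   - scRNA_PP7_b1 swaps the MS2 hairpin for a PP7 hairpin;
#   - sgRNA2.0 embeds two MS2 hairpins within internal backbone hairpins
#     and retains the terminator.
# Replace the `sequence` fields with the real supplementary sequences to
# design constructs for the bench; all structural validation logic is
# unchanged. Annotation intervals are 1-based inclusive coordinates within
# the template string, counting the literal "[SPACER]" token.
templates:
  gRNA:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGCUUUUUU"
    annotations:
      - { label: tracr_terminator, start: 70, end: 90 }
  scRNA_original:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGCUUUUUUACAUGAGGAUCACCCAUGU"
    annotations:
      - { label: tracr_terminator, start: 70, end: 90 }
      - { label: MS2, start: 91, end: 109 }
  scRNA.b1:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGACAUGAGGAUCACCCAUGU"
    annotations:
      - { label: MS2, start: 70, end: 88 }
  scRNA.b2:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUUACAUGAGGAUCACCCAUGU"
    annotations:
      - { label: MS2, start: 70, end: 88 }
  scRNA_2xMS2:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGACAUGAGGAUCACCCAUGUACAAACAUGAGGAUCACCCAUGU"
    annotations:
      - { label: MS2, start: 70, end: 88 }
      - { label: MS2, start: 93, end: 111 }
  scRNA_PP7_b1:
    sequence: "[SPACER]GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGGGAGCAGACGAUAUGGCGUCGCUCC"
    annotations:
      - { label: PP7, start: 70, end: 94 }
  sgRNA2.0:
    sequence: "[SPACER]GUUUUAGAGCUAGACAUGAGGAUCACCCAUGUAAAUAGCAAGUUAAAAUAAGGCUAGUCCACAUGAGGAUCACCCAUGUGUUAUCAACUUGAAAAAGUGGCACCGAGUCGGUGCUUUUUU"
    annotations:
      - { label: MS2, start: 22, end: 40 }
      - { label: MS2, start: 69, end: 87 }
      - { label: tracr_terminator, start: 108, end: 128 }
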
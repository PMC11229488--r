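# Illustrative motif catalog (synthetic subset, not an exhaustive
# published collection): a few DNA motifs classically discussed as
# potential double-strand-break mediators, for demonstrating the
# scanning and proximity-testing machinery.
motifs:
  - name: topoII_consensus
    kind: iupac
    pattern: RNYNNCNNGYNGKTNYNY
    max_mismatches: 2
  - name: Ig_switch_GAGCT
    kind: iupac
    pattern: GAGCT
    max_mismatches: 0
  - name: Ig_switch_GGGGT
    kind: iupac
    pattern: GGGGT
    max_mismatches: 0
  - name: CCND1_MTC_like
    kind: iupac
    pattern: GGGNNGGGG
    max_mismatches: 1
  - name: RSS12
    kind: rss
    spacer: 12
    mm_nonamer: 1
  - name: RSS23
    kind: rss
    spacer: 23
    mm_nonamer: 1
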
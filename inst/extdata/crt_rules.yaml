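# Ordered arrangement rules for carotenoid gene neighborhoods.
# First matching rule wins; edit or reorder freely.  Each rule may demand
# gene presences (cluster or scattered), absences, and ordered adjacencies
# (pairs tested against the signature's gap-bounded adjacency list).
rules:
  - label: IV
    require_present: [crtB, log, crtI, crtY, hyp, crtW]
    require_adjacent:
      - [crtW, crtZ]
  - label: III
    require_present: [crtB, log, crtI, crtY, crtW]
    require_absent: [hyp]
    require_adjacent:
      - [crtW, crtZ]
  - label: II
    require_present: [crtB, log, crtI, crtY, hyp]
    require_absent: [crtW]
  - label: I
    require_present: [crtB, log, crtI, crtY]
    require_absent: [hyp, crtW]
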
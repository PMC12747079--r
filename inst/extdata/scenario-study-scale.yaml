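# Study-scale synthetic scenario: ~5 Mb host genome carrying three
# implanted polinton-like elements, a 671-kb giant-virus-like reference
# with a 27-kb metagenomic island at 425-452 kb, a 263-row survey table and
# three growth replicates (one collapsing). One element per contig.
host:
  n_contigs: 12
  length_range: [300000, 500000]
  gc: 0.52
  telomere_motif: TTAGGG
  end_plan: [both, both, both, both, both, both, one, one, one, none, none, both]
eves:
  - contig: C2
    pos: 120000
    length: 20290
    gc: 0.35
    repeat_kind: TIR
    repeat_len: 488
    tsd_len: 5
    anchors: [MAGWNDKTHQLV]
    integrase: rve-INT
  - contig: C5
    pos: 200000
    length: 14500
    gc: 0.35
    repeat_kind: TDR
    repeat_len: 266
    tsd_len: 0
    anchors: [MAGWNDKTHQLV]
    integrase: YREC
  - contig: C8
    pos: 90000
    length: 32000
    gc: 0.35
    repeat_kind: TIR
    repeat_len: 500
    tsd_len: 6
    anchors: [MAGWNDKTHQLV, MHEVLRKPTWDY]
    integrase: rve-INT
gv:
  name: GV1
  length: 671000
  gc: 0.30
  island: [425001, 452000]
  n_reads: 25000
  read_len: 150
  library_size: 1000000
  bin: 100
  max_depth: 0
  island_min_len: 5000
survey:
  n_samples: 263
  hnf_mean: 1500
  cry1a_beta: [0.73, 3.69]
  threshold: 0.5
growth:
  replicates: 3
  inoculum: 200
  lag: 168
  mu: 0.02390
  cv: 0.1
  timepoints: [0, 24, 48, 72, 96, 120, 144, 168, 192, 216, 240, 264, 288,
               312, 336, 360, 384, 408, 432, 456, 480, 504, 528, 552]
  collapse_replicates: [3]
  t_collapse: 456
  collapse_frac: 0.8
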
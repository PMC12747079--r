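# Small demo scenario used in the documentation: fast to run, same shape as
# the study-scale scenario.
host:
  n_contigs: 3
  length_range: [120000, 160000]
  gc: 0.52
  telomere_motif: TTAGGG
  end_plan: [both, one, none]
eves:
  - contig: C1
    pos: 40000
    length: 18000
    gc: 0.35
    repeat_kind: TIR
    repeat_len: 488
    tsd_len: 5
    anchors: [MAGWNDKTHQLV]
    integrase: rve-INT
  - contig: C2
    pos: 60000
    length: 15000
    gc: 0.35
    repeat_kind: TDR
    repeat_len: 266
    tsd_len: 0
    anchors: [MAGWNDKTHQLV]
    integrase: YREC
gv:
  name: GV1
  length: 80000
  gc: 0.30
  island: [30001, 42000]
  n_reads: 4000
  read_len: 150
  library_size: 100000
survey:
  n_samples: 120
  hnf_mean: 1500
  cry1a_beta: [0.73, 3.69]
growth:
  replicates: 2
  inoculum: 200
  lag: 168
  mu: 0.02390
  cv: 0.1
  timepoints: [0, 24, 48, 72, 96, 120, 144, 168, 192, 216, 240, 264, 288,
               312, 336, 360, 384, 408, 432, 456, 480]
  collapse_replicates: [2]
  t_collapse: 432
  collapse_frac: 0.8
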
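Plain-text reference data shipped with crisprDiffSel.

hepg2_timecourse_lfc.tsv
  Reported per-gene log2 fold changes (Day 20 vs Day 0, Day 30 vs Day 0)
  for genes called growth-disadvantage (2D and 3D blocks) or
  growth-advantage (2D block) in time-course CRISPR screens of HepG2/C3A
  cells grown as 2D monolayers or 3D spheroids. All listed genes were
  significant at both timepoints in the originating screens, so
  classification demos set both significance flags to TRUE.

hepg2_depmap_essentiality.tsv
  Gene-effect (Chronos dependency) scores and essentiality labels for
  the growth-disadvantage genes above, as catalogued in the DepMap
  database; genes without DepMap coverage are absent from this table and
  receive "No data" on joining.
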
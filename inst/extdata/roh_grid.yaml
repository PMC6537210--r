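# Threshold-setting grid for the sliding-window ROH caller.
# Labels follow the "<window>snp_<min_kb>kb_<min_snps>snp_<het>_<missing>"
# naming scheme; omitted keys fall back to roh_params() defaults
# (density_kb: 50, max_gap_kb: 100, hit_threshold: 0.05).
settings:
  - {window_snps: 50, min_kb: 500, min_snps: 100, het: 0, missing: 0}
  - {window_snps: 50, min_kb: 500, min_snps: 100, het: 0, missing: 2}
  - {window_snps: 50, min_kb: 500, min_snps: 100, het: 1, missing: 2}
  - {window_snps: 50, min_kb: 500, min_snps: 100, het: 1, missing: 5}
  - {window_snps: 50, min_kb: 500, min_snps: 15, het: 0, missing: 1}
  - {window_snps: 50, min_kb: 500, min_snps: 50, het: 0, missing: 1}
  - {window_snps: 500, min_kb: 500, min_snps: 50, het: 0, missing: 1}
  - {window_snps: 50, min_kb: 500, min_snps: 50, het: 0, missing: 1, pruned: true}
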
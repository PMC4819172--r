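# Default per-feature error statistics (mean M, standard deviation SD of
# feature-minus-true-GDT-TS errors). Two entries are published constants:
# the ModelEvaluator error mean (-0.0219, the least biased feature, with the
# smallest spread) and the Euclidean compact score's mean error (0.4119, the
# largest of the 11). All other entries are illustrative placeholders with
# the same qualitative profile; retrain with train_error_stats() on your own
# (feature, GDT-TS) pairs for production scoring. n = 0 marks entries not
# fitted from data.
error_stats:
  rf_cb_srs_od: {M: 0.05, SD: 0.15, n: 0}
  ss_similarity: {M: 0.10, SD: 0.12, n: 0}
  ss_penalty: {M: -0.05, SD: 0.18, n: 0}
  euclidean_compact: {M: 0.4119, SD: 0.15, n: 0}
  surface_nonpolar: {M: -0.10, SD: 0.20, n: 0}
  exposed_mass: {M: 0.05, SD: 0.20, n: 0}
  exposed_surface: {M: 0.10, SD: 0.18, n: 0}
  sa_similarity: {M: 0.12, SD: 0.15, n: 0}
  rwplus: {M: 0.05, SD: 0.16, n: 0}
  modeleval: {M: -0.0219, SD: 0.08, n: 0}
  dope: {M: 0.03, SD: 0.14, n: 0}
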
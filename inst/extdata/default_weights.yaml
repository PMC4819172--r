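# Published combination weights for the 11 canonical features, fitted by
# coordinate descent against per-target GDT-TS loss on a CASP training pool.
weights:
  rf_cb_srs_od: 0.03
  ss_similarity: 0.09
  ss_penalty: 0.04
  euclidean_compact: 0.08
  surface_nonpolar: 0.08
  exposed_mass: 0.01
  exposed_surface: 0.03
  sa_similarity: 0.10
  rwplus: 0.00
  modeleval: 0.09
  dope: -0.02
min_loss: .na.real
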
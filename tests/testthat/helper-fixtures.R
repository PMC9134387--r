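# Session-memoized fixtures: built once per test run, in code, no stored data.
options(snapqsar.verbose = FALSE)

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, compute) {
  if (is.null(.fx[[key]])) .fx[[key]] <- compute()
  .fx[[key]]
}

# Small embedded synthetic library used across unit tests.
fx_embedded <- function() fx_memo("embedded", function() {
  lib <- generate_library(synth_config(n_compounds = 24, seed = 5))
  embed_library(lib, seed = 1)
})

fx_render_params <- function() render_params(image_px = 48L)

fx_manifest <- function() fx_memo("manifest", function() {
  dir <- file.path(tempdir(), "snapqsar_fx_images")
  snapshot_library(fx_embedded(), fx_render_params(), dir)
})

fx_labels <- function() {
  emb <- fx_embedded()
  stats::setNames(vapply(emb, `[[`, 0L, "class_label"),
                  vapply(emb, `[[`, "", "compound_id"))
}

fx_descriptors <- function() fx_memo("descriptors", function()
  compute_descriptors(fx_embedded()))

# A tiny trained classifier shared by classifier-contract tests.
fx_classifier <- function() fx_memo("classifier", function() {
  man <- fx_manifest()
  labels <- fx_labels()
  ids <- unique(man$compound_id)
  tr <- ids[seq_len(18L)]
  va <- setdiff(ids, tr)
  m_tr <- man[man$compound_id %in% tr, , drop = FALSE]
  m_va <- man[man$compound_id %in% va, , drop = FALSE]
  list(model = train_classifier(m_tr, labels, m_va, labels,
                                classifier_config(epochs = 4L, seed = 11L,
                                                  image_edge_px = 24L)),
       m_tr = m_tr, m_va = m_va, labels = labels)
})

# Full-scale benchmark (five patterns, both arms) with the image-signal
# term switched on and off; computed once and reused by the acceptance
# tests. Both runs share one run directory so structure-dependent stages
# (conformers, renders, descriptors) are cache-shared.
fx_benchmark <- function(gamma) {
  key <- sprintf("benchmark_g%g", gamma)
  fx_memo(key, function() {
    out_dir <- file.path(tempdir(), "snapqsar_benchmark")
    cfg <- run_config(
      synth = synth_config(n_compounds = 300, seed = 1,
                           image_signal_weight = gamma),
      seed = 1, out_dir = out_dir)
    run_pipeline(cfg)
  })
}
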
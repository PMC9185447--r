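# Expensive shared fixtures, built once per test run.
fixture_env <- new.env(parent = emptyenv())

# Full easy-preset corpus (default generator conditions), harmonized,
# segmented at 1 s / 80% and extracted: ~5,500-6,000 windows.
easy_fixture <- function() {
  if (is.null(fixture_env$easy)) {
    corpus <- synth_corpus(generator_config(), seed = 2024)
    streams <- harmonize_corpus(corpus$recordings, corpus$manifests)
    ws <- segment_streams(streams, segmentation_config(1, 0.8))
    fm <- extract_features(ws)
    fixture_env$easy <- list(corpus = corpus, streams = streams,
                             ws = ws, fm = fm)
  }
  fixture_env$easy
}
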
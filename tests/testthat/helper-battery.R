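# The 50-image default battery and its evaluation are shared between the
# localization and segmentation acceptance checks (one run, as they are
# defined over the same images). Cached per test session.

.battery_cache <- new.env(parent = emptyenv())

battery_results <- function() {
  if (is.null(.battery_cache$res)) {
    b <- synth_battery(50, master_seed = 0)
    .battery_cache$battery <- b
    .battery_cache$res <- od_batch(b)
  }
  .battery_cache$res
}
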
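.onLoad <- function(libname, pkgname) {
  register_backend("oracle", oracle_backend)
  register_backend("empty", empty_backend)
  register_backend("threshold", threshold_backend)
  register_backend("pixelmlp", train_backend)
  invisible()
}
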
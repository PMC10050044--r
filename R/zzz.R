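.onLoad <- function(libname, pkgname) {
  # block samplers for logistic models; idempotent
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
}
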
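#' @useDynLib spikewavformer, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.onLoad <- function(libname, pkgname) {
  # Serial BLAS: deterministic numerics and no thread oversubscription when
  # the process is confined to a single core.
  try(cpp_set_blas_threads(1L), silent = TRUE)
  invisible()
}
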
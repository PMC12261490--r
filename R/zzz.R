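#' @useDynLib marlene, .registration = TRUE
#' @importFrom stats runif rnorm rgamma rpois rbinom phyper p.adjust median cor setNames
#' @importFrom utils read.delim write.table
NULL

.onLoad <- function(libname, pkgname) {
  # tiny dense kernels; threaded BLAS oversubscription only adds latency
  try(.Call("marlene_set_blas_threads", 1L, PACKAGE = "marlene"),
      silent = TRUE)
  invisible(NULL)
}
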
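#' @useDynLib mlnalign, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pf pchisq pbinom sd setNames runif rnorm
#' @importFrom utils head tail read.table write.table packageVersion
NULL
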
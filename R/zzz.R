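#' DomainScout: conserved-domain discovery from seed protein families
#'
#' Conservation profiling and domain delimitation, profile-HMM iterative
#' database search, domain-architecture census, and sequence- and
#' structure-based distance trees, with seeded generators of ground-truthed
#' synthetic inputs.
#'
#' @useDynLib DomainScout, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"
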
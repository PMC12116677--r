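#' Derive a stage seed from a global seed
#'
#' All randomness in the pipeline flows from one global seed; each stage
#' (clustering, within-cluster sampling, test split, ...) uses a seed
#' offset by a polynomial hash of the stage name, so stages are
#' independently reproducible and do not collide. The result always lies
#' in `[0, 2^31 - 2]`.
#'
#' @param seed global integer seed
#' @param stage stage name
#' @return derived integer seed
#' @export
deriveSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) + h) %% 2147483646)
}
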
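#' @useDynLib scseVNet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif quantile median sd
#' @importFrom utils write.csv
NULL

# Typed conditions: every contract violation raised by this package carries a
# specific condition class so callers (and tests) can distinguish a missing
# modality from, say, a label-domain violation.
vnetStop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "vnetError"),
                      call = sys.call(-1)))
}

missingModalityError  <- function(modality)
  vnetStop("MissingModalityError", "missing modality file: %s", modality)
shapeMismatchError    <- function(msg, ...) vnetStop("ShapeMismatchError", msg, ...)
labelDomainError      <- function(msg, ...) vnetStop("LabelDomainError", msg, ...)
degenerateInputError  <- function(msg, ...) vnetStop("DegenerateInputError", msg, ...)
patchTooLargeError    <- function(msg, ...) vnetStop("PatchTooLargeError", msg, ...)
channelParityError    <- function(msg, ...) vnetStop("ChannelParityError", msg, ...)
configError           <- function(msg, ...) vnetStop("ConfigError", msg, ...)
emptyDatasetError     <- function(msg, ...) vnetStop("EmptyDatasetError", msg, ...)
missingPairError      <- function(msg, ...) vnetStop("MissingPairError", msg, ...)
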
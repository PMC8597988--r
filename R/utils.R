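#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Experiments fan a single master seed out to named stages (cohort
#' generation, classifier training, subsampling, ...) so that adding a stage
#' never perturbs the random stream of an earlier one. The derivation is a
#' small deterministic integer hash of the label folded into the master seed;
#' results always lie in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param label character stage name.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "cohort") != derive_seed(1, "train")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  h <- (h + (as.numeric(master) %% 2147483647) * 2654435) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# argmax with deterministic tie-break by position (domain order)
argmax_first <- function(x) which(x == max(x))[1L]
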
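#' Derive a reproducible sub-seed from a global seed and a label
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Independent stages (weight initialization, dropout, fold splits, Monte
#' Carlo runs) draw their own sub-seed so that changing one stage's usage
#' pattern does not perturb the others.
#'
#' @param seed Integer global seed.
#' @param salt Character label of the consuming stage.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt))) %% 2147483647
  s <- (abs(seed) %% 2147483647) * 48271 + h * 7919
  as.integer(s %% 2147483646 + 1)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# condition class used by the CLI to distinguish bad configuration (exit 2)
# from runtime failure (exit 1)
config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
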
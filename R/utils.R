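# Internal helpers shared across modules.

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabet order used throughout the package for emission vectors and
#' background distributions.
#'
#' @format character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derived from a global seed and a stage name,
# so toggling one stage does not shift another stage's random stream.
stageSeed <- function(seed, stage) {
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Named background distributions over AA_ALPHABET.
backgroundFrequencies <- function(background = c("uniform", "blosum62")) {
  background <- match.arg(background)
  if (background == "uniform") {
    stats::setNames(rep(1 / 20, 20L), AA_ALPHABET)
  } else {
    .BLOSUM62_BG
  }
}

.asBackground <- function(background) {
  if (is.character(background)) return(backgroundFrequencies(background))
  stopifnot(is.numeric(background), length(background) == 20L,
            all(background > 0), abs(sum(background) - 1) < 1e-6)
  stats::setNames(background / sum(background), AA_ALPHABET)
}

.charsToIdx <- function(chars) match(chars, AA_ALPHABET)

.splitRow <- function(row) strsplit(row, "", fixed = TRUE)[[1L]]

# log2-sum-exp of two values
.l2se <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log2(2^(a - m) + 2^(b - m)))
}
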
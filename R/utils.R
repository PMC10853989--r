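#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline (cohort simulation, fold
#' assignment, per-fold autoencoder and MLP initialisation, upsampling)
#' draws its own seed from the single master seed through this splitmix-style
#' mixer, so each stage can be re-run in isolation and still reproduce the
#' full run. The tag is hashed character-by-character into the state before
#' mixing.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the consumer (e.g. `"cv/rep2/fold3"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1L, "cohort")
#' deriveSeed(1L, "cv/rep1/fold1")
#' @export
deriveSeed <- function(seed, tag = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- as.double(seed %% m)
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% m
  }
  # two rounds of multiplicative mixing (Lehmer-style) to decorrelate
  # neighbouring seeds and tags
  h <- (h * 48271) %% m
  h <- (h * 16807 + 2654435769 %% m) %% m
  as.integer(h %% (m - 2) + 1)
}

# short stable hash of an R object (FNV-1a over its deparsed form),
# used for provenance sidecars
.configHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.datatable.aware <- TRUE

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# one-hot indicator matrix for a factor, columns in level order
.oneHot <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}
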
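# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All simulators route randomness
# through this so that a master seed gives bit-identical output regardless
# of what the caller's RNG has been doing.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed for a named stream (library id, stage name ...).
# Keeps every derived seed in [1, 2^31 - 2].
child_seed <- function(seed, key) {
  m <- 2147483629
  h <- as.numeric(seed) %% m
  for (v in utf8ToInt(as.character(key))) h <- (h * 131 + v) %% m
  as.integer(h %% (m - 1L) + 1)
}

# Negative-binomial draw parameterized by mean mu and dispersion alpha with
# variance mu + alpha * mu^2; alpha = 0 degenerates to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion < 0) stop("dispersion must be non-negative", call. = FALSE)
  if (dispersion == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

geometric_mean <- function(x) exp(mean(log(x)))

# Reverse complement of a DNA character string (base-R hot path; Biostrings
# is reserved for file I/O).
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
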
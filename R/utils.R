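# Internal helpers: deterministic substreams and small checks.

#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary set of labels (subject id,
#' stream name, replicate index, ...) into a 31-bit integer seed. Subject-wise
#' substreams make cohort generation invariant to the number of other
#' subjects: adding subject 25 never perturbs subjects 1-24.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "subject", 3)
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  codes <- utf8ToInt(labels)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (cc in codes) h <- (h * 31 + cc) %% m
  as.integer(h)
}

# stop() with a consistent error class so callers can distinguish user input
# errors from genuine bugs
knob_stop <- function(msg, class) {
  stop(structure(class = c(class, "knobmap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# polynomial hash of a character scalar, returned as 8-hex-digit string; used
# for the pipeline manifest (no cryptographic intent).
text_hash <- function(txt) {
  codes <- utf8ToInt(txt)
  m <- 2147483647
  h <- 17
  for (cc in codes) h <- (h * 31 + cc) %% m
  sprintf("%08x", as.integer(h))
}

# lognormal meanlog/sdlog for a given mean and coefficient of variation
lognorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}
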
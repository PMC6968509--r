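# internal helpers shared across modules

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so seeded package functions do not clobber
#' the user's random stream.
#' @noRd
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## derive a stage-specific sub-seed from a master seed; keeps results
## reproducible while letting stages be re-run independently
deriveSeed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

## FNV-1a 32-bit hash of a character scalar; used for config provenance
fnv1aHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648 - (h %% 2147483648 > 2147483647)),
                 as.integer(b))
    h <- (as.numeric(h %% 4294967296) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## closed vocabularies
.MATRICES <- c("serum", "liver", "urine")
.PHASES <- c("water", "lipid")
.GROUPS <- c("healthy", "LDA", "RDA")
.PULSE_PROGRAMS <- c("NOESY", "CPMG")

checkVocab <- function(value, vocab, what) {
  if (length(value) != 1L || !value %in% vocab)
    stopf("%s must be one of: %s (got '%s')", what,
          paste(vocab, collapse = ", "), paste(value, collapse = ","))
  value
}

## trapezoidal integral of y over x (ascending x)
trapzInt <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
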
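# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# route through this so that a single integer seed fixes every draw.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stage index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ix) s <- (s * 69069 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

# Unicode NFC normalization of character data; NA passes through.
nfc <- function(x) {
  if (length(x) == 0) return(x)
  out <- x
  ok <- !is.na(x)
  out[ok] <- stringi::stri_trans_nfc(enc2utf8(x[ok]))
  out
}

# Progress/record-count logging to stderr.
log_info <- function(...) message("[humtag] ", ...)

stop_if_not <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x)

fmt_num <- function(x) sprintf("%.17g", x)
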
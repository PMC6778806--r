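# Shared low-level helpers. Sequences are stored as integer vectors over
# 1:4 = A,C,G,T; conversion to character strings happens only at I/O
# boundaries (FASTA, VCF, alignment).

BASES <- c("A", "C", "G", "T")

seq_to_string <- function(x) paste(BASES[x], collapse = "")

string_to_seq <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], BASES)
  if (anyNA(x)) stop("sequence contains characters outside {A,C,G,T}")
  x
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed derived from a master seed, so stages can be
# rerun in isolation with the stream they had inside the full pipeline.
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}
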
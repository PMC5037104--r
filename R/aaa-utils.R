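# Internal helpers shared across modules.

# Base <-> integer code lookup (A=1, C=2, G=3, T=4; anything else 0).
.BASE_CODE <- local({
  x <- integer(256)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})
.BASES <- c("A", "C", "G", "T")

.base_codes <- function(seq) .BASE_CODE[as.integer(charToRaw(seq))]

# Gene id of a transcript id: strip a trailing splice-variant suffix ".<n>".
.gene_of <- function(transcript_id) sub("\\.[0-9]+$", "", transcript_id)

# Truncate (not round) a percentage to `digits` decimals, as printed
# assignable-read percentages are truncated.
.trunc_pct <- function(x, digits = 2L) trunc(x * 10^digits) / 10^digits

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    .stopf("'%s' must be in [0, 1]", name)
  invisible(x)
}

# Draw n reproducible sub-seeds (< 2^31) from one master seed without
# leaving the global RNG in a caller-visible state.
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.is_reads_df <- function(x) {
  is.data.frame(x) && all(c("read_id", "sequence", "quality") %in% names(x))
}

.check_reads <- function(reads) {
  if (!.is_reads_df(reads))
    .stopf("reads must be a data.frame with read_id, sequence, quality")
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    .stopf("sequence and quality lengths differ for some reads")
  invisible(reads)
}

.check_reference <- function(reference) {
  if (!is.character(reference) || length(reference) == 0L ||
      is.null(names(reference)) || any(!nzchar(names(reference))))
    .stopf("reference must be a non-empty named character vector of sequences")
  invisible(reference)
}
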
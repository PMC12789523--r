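# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed
#'
#' A single pipeline seed fans out deterministically to per-stage seeds so
#' that stages can be re-run in isolation. Kept below 2^31 - 1.
#' @noRd
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (abs(as.numeric(seed)) %% 2147483646) + 1
  as.integer((s * 48271 + 7919 * as.numeric(k)) %% 2147483647L + 1)
}

#' Run an expression with a locally set RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  invisible(x)
}

# Soft-clip bookkeeping from a CIGAR string: leading/trailing S lengths and
# the width consumed on the reference (M/D/N/=/X).
parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  lead <- integer(length(cigar))
  trail <- integer(length(cigar))
  refw <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    o <- ops[[i]]
    if (length(o) == 0L || cigar[i] == "*") next
    len <- as.integer(sub("[MIDNSHP=X]", "", o))
    op <- substr(o, nchar(o), nchar(o))
    if (op[1L] == "S") lead[i] <- len[1L]
    if (length(o) > 1L && op[length(o)] == "S") trail[i] <- len[length(o)]
    refw[i] <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  }
  data.frame(lead_clip = lead, trail_clip = trail, ref_width = refw)
}
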
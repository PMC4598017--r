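# Internal helpers shared across modules.

# Derive a stage-specific RNG seed from a global seed; kept below 2^31-1.
derive_seed <- function(seed, label) {
  (abs(as.integer(seed)) + sum(utf8ToInt(label)) * 10007L) %% 2147483647L
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings (byte comparison).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming() requires equal-length strings")
  sum(ra != rb)
}

split_codons <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

upper_tri <- function(m) m[upper.tri(m)]

# Round half away from zero to integer (base round() is banker's rounding).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    # pathological all-zero draw (extremely small alphas): fall back to the
    # normalized alphas themselves
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

check_square_labeled <- function(d, arg = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop(sprintf("'%s' must be a square matrix", arg))
  if (!isTRUE(all.equal(unname(d), unname(t(d)), tolerance = 1e-8))) {
    stop(sprintf("'%s' must be symmetric", arg))
  }
  d
}
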
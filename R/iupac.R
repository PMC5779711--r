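# IUPAC alphabet utilities. Sequences are upper-case top-strand strings;
# degenerate symbols are legal in molecules (synthesized/ambiguous DNA).

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_CHARS <- names(IUPAC_BITS)

.iupac_lookup <- local({
  tab <- integer(128)
  tab[utf8ToInt(paste(IUPAC_CHARS, collapse = ""))] <- IUPAC_BITS
  tab
})

#' Validate and normalize a DNA string
#'
#' Upper-cases the input and checks every character against the IUPAC DNA
#' alphabet (ACGTRYSWKMBDHVN).
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return the normalized string.
#' @keywords internal
normalize_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  codes <- utf8ToInt(x)
  if (length(codes) > 0L && any(codes > 127L | .iupac_lookup[codes] == 0L)) {
    bad <- unique(strsplit(x, "", fixed = TRUE)[[1]])
    bad <- bad[!bad %in% IUPAC_CHARS]
    stop(what, " contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

# integer bit vector (one element per base) for subset matching
seq_bits <- function(x) {
  codes <- utf8ToInt(x)
  .iupac_lookup[codes]
}

#' Reverse complement of a DNA string
#'
#' Degenerate IUPAC symbols are complemented set-wise (R <-> Y, B <-> V, ...).
#'
#' @param x DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if the string contains only concrete bases
is_concrete_dna <- function(x) {
  !grepl("[^ACGT]", x)
}

# All 0-based start positions where `pattern` (IUPAC) matches `subject`.
# A pattern symbol matches a subject symbol iff the subject's base set is a
# subset of the pattern's set (so pattern N matches anything, but pattern A
# does not match subject N: no fabricated matches).
iupac_match_starts <- function(subject, pattern) {
  n <- nchar(subject)
  m <- nchar(pattern)
  if (m == 0L || m > n) return(integer(0))
  sb <- seq_bits(subject)
  pb <- seq_bits(pattern)
  npos <- n - m + 1L
  ok <- rep(TRUE, npos)
  for (j in seq_len(m)) {
    sj <- sb[j:(j + npos - 1L)]
    ok <- ok & bitwAnd(sj, bitwNot(pb[j])) == 0L
  }
  which(ok) - 1L
}

# substring by 0-based half-open interval
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# rotate a circular sequence so that 0-based position `k` becomes position 0
rotate_seq <- function(x, k) {
  n <- nchar(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  paste0(substr(x, k + 1L, n), substr(x, 1L, k))
}

# Booth's algorithm: index (0-based) of the lexicographically least rotation
least_rotation_index <- function(x) {
  s <- utf8ToInt(paste0(x, x))
  n2 <- length(s)
  f <- rep(-1L, n2)
  k <- 0L
  for (j in seq.int(1L, n2 - 1L)) {
    sj <- s[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}
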
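## Exact 2-bit k-mer packing in base R. A 31-mer code needs 62 bits, past
## the 53-bit exact-integer range of a double, so codes are carried as a
## (hi, lo) pair: hi packs the leading k - kl bases, lo the trailing
## kl = min(15, k) bases, and code = hi * 4^kl + lo. Both halves stay
## below 2^32, so every intermediate here is exact in double arithmetic;
## the public representation is the full code as a decimal string.

## A=0, C=1, G=2, T=3 (so numeric order on codes equals lexicographic
## order on sequences); NA for anything else.
baseCodes <- function(seq) {
  v <- utf8ToInt(seq)
  out <- rep(NA_real_, length(v))
  out[v == 65L | v == 97L] <- 0
  out[v == 67L | v == 99L] <- 1
  out[v == 71L | v == 103L] <- 2
  out[v == 84L | v == 116L] <- 3
  out
}

## (hi, lo) halves for every k-mer window of a base-code vector; rows with
## a non-ACGT base come out NA. Big-endian: first base most significant.
kmerHiLo <- function(b, k) {
  m <- length(b) - k + 1L
  if (m < 1L) return(NULL)
  kl <- min(15L, k)
  kh <- k - kl
  E <- embed(b, k)                       # E[i, j] = b[i + k - j]
  X <- E[, k:1, drop = FALSE]            # X[i, j] = b[i + j - 1]
  hi <- if (kh > 0L) as.numeric(X[, 1:kh, drop = FALSE] %*% 4^((kh - 1):0))
        else numeric(m)
  lo <- as.numeric(X[, (kh + 1L):k, drop = FALSE] %*% 4^((kl - 1):0))
  cbind(hi = hi, lo = lo)
}

## Canonical (hi, lo) per window: the smaller of each k-mer's code and its
## reverse complement's.
canonicalHiLo <- function(b, k) {
  f <- kmerHiLo(b, k)
  if (is.null(f)) return(NULL)
  r <- kmerHiLo(3 - rev(b), k)
  r <- r[nrow(r):1, , drop = FALSE]      # align rc window i with forward i
  useF <- f[, 1] < r[, 1] | (f[, 1] == r[, 1] & f[, 2] <= r[, 2])
  cbind(hi = ifelse(useF, f[, 1], r[, 1]),
        lo = ifelse(useF, f[, 2], r[, 2]))
}

## Exact decimal string of hi * 4^kl + lo (schoolbook arithmetic on
## base-10 digit vectors; every intermediate < 2^52).
hiLoToDecimal <- function(hi, lo, kl) {
  M <- 4^kl
  vapply(seq_along(hi), function(i) {
    if (is.na(hi[i]) || is.na(lo[i])) return(NA_character_)
    if (hi[i] == 0) return(sprintf("%.0f", lo[i]))
    d <- rev(as.numeric(strsplit(sprintf("%.0f", hi[i]), "")[[1]]))
    carry <- lo[i]
    out <- numeric(0)
    for (dig in d) {
      t <- dig * M + carry
      out <- c(out, t %% 10)
      carry <- (t - t %% 10) / 10
    }
    while (carry > 0) {
      out <- c(out, carry %% 10)
      carry <- (carry - carry %% 10) / 10
    }
    paste(rev(out), collapse = "")
  }, character(1))
}

## Inverse: decimal string -> c(hi, lo) by long division by 4^kl.
decimalToHiLo <- function(code, kl) {
  M <- 4^kl
  d <- as.numeric(strsplit(code, "")[[1]])
  q <- numeric(length(d))
  r <- 0
  for (i in seq_along(d)) {
    t <- r * 10 + d[i]
    q[i] <- (t - t %% M) / M
    r <- t %% M
  }
  hi <- 0
  for (qd in q) hi <- hi * 10 + qd      # quotient < 2^32: exact
  c(hi = hi, lo = r)
}

## Unpack an exact (hi, lo) pair into the k-mer string.
hiLoToKmer <- function(hi, lo, k) {
  kl <- min(15L, k)
  kh <- k - kl
  unpack <- function(x, n) {
    out <- integer(n)
    for (i in n:1) {
      out[i] <- x %% 4
      x <- (x - out[i]) / 4
    }
    out
  }
  paste(c("A", "C", "G", "T")[c(unpack(hi, kh), unpack(lo, kl)) + 1L],
        collapse = "")
}
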
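# Independent brute-force oracles. These are deliberately naive and slow:
# plain-R dynamic programming / scanning, sharing no code with the package.

# full-matrix affine-gap Smith-Waterman (Gotoh), gap of length k costs
# open + k * ext; returns the optimal local score (0 allows empty alignment)
oracle_sw <- function(query, ref, match = 1, mismatch = 3, open = 5, ext = 2) {
  q <- strsplit(query, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)   # best ending at (i,j)
  E <- matrix(NEG, n + 1, m + 1) # gap in query (consuming ref)
  F <- matrix(NEG, n + 1, m + 1) # gap in ref (consuming query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- if (q[i - 1] == r[j - 1] && q[i - 1] %in% c("A", "C", "G", "T"))
        match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# left-to-right per-position scan for the first recognition-site occurrence,
# comparing read letters against explicit IUPAC base sets; N in the read is
# in no set. Returns the 0-based site index or NA.
oracle_first_site <- function(sequence, recognition) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
               S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
               V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
               B = c("C", "G", "T"), N = c("A", "C", "G", "T"))
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(recognition, "")[[1]]
  k <- length(p)
  if (length(s) < k) return(NA_integer_)
  for (start in 0:(length(s) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[start + j] %in% sets[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) return(start)
  }
  NA_integer_
}

# brute-force normalized cross-correlation by explicit double loop
oracle_xcorr <- function(dvec, evec, max_lag) {
  n <- length(dvec)
  norm <- sqrt(sum(dvec^2)) * sqrt(sum(evec^2))
  lags <- (-max_lag):max_lag
  coef <- numeric(length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    acc <- 0
    for (i in 1:n) {
      j <- i - l
      if (j >= 1 && j <= n) acc <- acc + dvec[j] * evec[i]
    }
    coef[li] <- acc / norm
  }
  list(lags = lags, coefficients = coef)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
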
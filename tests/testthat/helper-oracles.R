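# Independent oracles, deliberately implemented by enumeration rather than
# convolution so they exercise a different code path than the package.

# All compositions of k atoms among m isotope slots (k1,...,km, sum k).
compositions <- function(k, m) {
  if (m == 1L) return(matrix(k, ncol = 1L))
  out <- list()
  for (k1 in 0:k) {
    rest <- compositions(k - k1, m - 1L)
    out[[length(out) + 1L]] <- cbind(k1, rest)
  }
  do.call(rbind, out)
}

# Shift distribution of one element with k atoms, by multinomial enumeration.
element_shift_oracle <- function(abund, k) {
  m <- length(abund)
  shifts <- 0:(m - 1L)
  comp <- compositions(k, m)
  probs <- apply(comp, 1L, function(ki) {
    exp(lgamma(k + 1) - sum(lgamma(ki + 1)) + sum(ki * log(abund)))
  })
  total <- as.integer(comp %*% shifts)
  out <- numeric(k * (m - 1L) + 1L)
  for (i in seq_along(total)) out[total[i] + 1L] <- out[total[i] + 1L] + probs[i]
  out
}

# Full-molecule shift distribution by enumerating the cross product of
# per-element shift totals.
oracle_shift_distribution <- function(f, exclude_backbone_c = 0L,
                                      table = isotope_table()) {
  if (is.character(f)) f <- parse_formula(f)
  counts <- f
  if ("C" %in% names(counts)) {
    counts[["C"]] <- counts[["C"]] - as.integer(exclude_backbone_c)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) return(1)
  per <- lapply(names(counts), function(el) {
    d <- element_shift_oracle(table[[el]], counts[[el]])
    list(shift = seq_along(d) - 1L, prob = d)
  })
  grid <- expand.grid(lapply(per, function(x) seq_along(x$prob)))
  prob <- rep(1, nrow(grid))
  shift <- rep(0L, nrow(grid))
  for (j in seq_along(per)) {
    prob <- prob * per[[j]]$prob[grid[[j]]]
    shift <- shift + per[[j]]$shift[grid[[j]]]
  }
  out <- numeric(max(shift) + 1L)
  for (i in seq_along(shift)) out[shift[i] + 1L] <- out[shift[i] + 1L] + prob[i]
  out
}

# Fragment CID under independent per-position labeling, by enumerating all
# 2^n isotopomers of the whole metabolite.
oracle_cid_enumeration <- function(p, backbone) {
  n <- length(p)
  cid <- numeric(length(backbone) + 1L)
  for (code in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    prob <- prod(ifelse(bits == 1L, p, 1 - p))
    k <- sum(bits[backbone])
    cid[k + 1L] <- cid[k + 1L] + prob
  }
  cid
}
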
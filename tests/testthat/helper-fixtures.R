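# Shared fixture builders; everything is generated in code under fixed seeds.

# Small fold-change matrix with optional missingness.
random_fc_matrix <- function(nr, nc, missing = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("t%02d", seq_len(nr)),
                              sprintf("e%02d", seq_len(nc))))
  if (missing > 0) m[runif(length(m)) < missing] <- NA
  m
}

# Naive pairwise-complete Pearson over co-observed entries: the independent
# double-loop oracle for the correlation stage.
naive_pairwise_pearson <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# Exact binomial upper tail by choose()-based enumeration (independent of
# dbinom): sum over j >= k of C(n, j) p^j (1-p)^(n-j).
enum_binom_tail <- function(n, p, k) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Exhaustive hypergeometric upper tail: enumerate all n-subsets of the
# universe and count those with >= k members in the category.
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- combn(N, n)
  incat <- colSums(subsets <= K)   # treat 1..K as the category
  mean(incat >= k)
}

# Brute-force PWM rescoring: score every offset independently of the
# package's windowing code.
brute_pwm_hits <- function(scores, maxScore, frac, seqchr) {
  w <- ncol(scores)
  chars <- strsplit(seqchr, "")[[1]]
  L <- length(chars)
  starts <- integer(0); vals <- numeric(0)
  if (L < w) return(data.frame(start = starts, score = vals))
  for (s in seq_len(L - w + 1)) {
    tot <- 0
    for (j in seq_len(w)) {
      b <- chars[s + j - 1]
      tot <- tot + if (b %in% c("A", "C", "G", "T")) scores[b, j] else -Inf
    }
    if (tot >= frac * maxScore) {
      starts <- c(starts, s); vals <- c(vals, tot)
    }
  }
  data.frame(start = starts, score = vals)
}

rc_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

random_dna <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
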
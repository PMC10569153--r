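# exact two-sided rank-sum p by full enumeration of rank assignments
enumerate_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  w_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(rank(pooled)[idx])) - n * (n + 1) / 2
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

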
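# Independent oracles, kept free of the code paths they check.

# hypergeometric upper tail by direct combinatorial enumeration
hyperTailOracle <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# AUROC as the fraction of positive/negative score comparisons won,
# ties counted half
aucOracle <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
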
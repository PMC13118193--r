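# Independent oracles used across tests.

# Holm adjustment via brute-force closed testing with Bonferroni local tests:
# adj p_i = max over all subsets S containing i of min(1, |S| * min_{j in S} p_j).
holm_oracle <- function(p) {
  m <- length(p)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  vapply(seq_len(m), function(i) {
    max(vapply(subsets, function(S)
      if (i %in% S) min(1, length(S) * min(p[S])) else 0, numeric(1)))
  }, numeric(1))
}

# AUC by exhaustive concordant-pair counting (ties count one half).
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  comp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(comp)
}

# standard prostate protocol used throughout
paper_scheme <- function() bvalue_scheme(c(0, 100, 500, 800, 1200, 2000), 5)
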
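# Independent brute-force oracles; deliberately naive implementations.

# AUC by exhaustive presence-absence pair enumeration, ties counted 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sa <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sa) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sa))
}

# kappa straight from the published formula
oracle_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  (po - pe) / (1 - pe)
}

oracle_tss <- function(tp, fp, tn, fn) {
  tp / (tp + fn) + tn / (tn + fp) - 1
}

# exhaustive threshold scan over 0, all score values +/- eps, and 1
oracle_max_tss <- function(scores, labels, eps = 1e-9) {
  cand <- sort(unique(c(0, scores - eps, scores, scores + eps, 1)))
  best <- -Inf
  for (th in cand) {
    tp <- sum(scores >= th & labels == 1)
    fn <- sum(scores < th & labels == 1)
    tn <- sum(scores < th & labels == 0)
    fp <- sum(scores >= th & labels == 0)
    best <- max(best, oracle_tss(tp, fp, tn, fn))
  }
  best
}

# minimal total within-class SSD over all ordered partitions of the
# sorted values into k non-empty contiguous classes (n <= ~15)
oracle_jenks_ssd <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  if (k == 1) return(ssd(v))
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- 0
    for (i in seq_len(k)) tot <- tot + ssd(v[(cuts[i] + 1):cuts[i + 1]])
    best <- min(best, tot)
  }
  best
}

# total within-class SSD induced by a set of breaks ("value > break" rule)
breaks_ssd <- function(values, breaks) {
  cls <- vapply(values, function(x) sum(x > breaks), numeric(1))
  sum(vapply(split(values, cls), function(x) sum((x - mean(x))^2), numeric(1)))
}
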
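# Independent brute-force oracles used to pin down the fast implementations.

# AUC by explicit pair counting: (#concordant + 0.5 #tied) / (npos * nneg)
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Youden maximizer by exhaustive scan over every candidate cutpoint
# (midpoints of consecutive distinct scores plus extremes), smallest wins
youdenOracle <- function(scores, labels) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  lo <- if (s[1] > 0) s[1] / 2 else s[1] - 1
  hi <- if (s[length(s)] < 1) (s[length(s)] + 1) / 2 else s[length(s)] + 1
  cand <- c(lo, mids, hi)
  bestJ <- -Inf; bestT <- NA
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    J <- sens + spec - 1
    if (J > bestJ + 1e-15) { bestJ <- J; bestT <- t }
  }
  bestT
}

# depth-1 regression split by naive O(n^2) scan; returns NULL when the best
# split reduces SSE by less than `gate`
stumpOracle <- function(v, a, gate = 0.05) {
  ok <- !is.na(v) & !is.na(a)
  v <- v[ok]; a <- a[ok]
  if (length(v) < 10 || length(unique(v)) < 2) return(NULL)
  sse0 <- sum((a - mean(a))^2)
  if (sse0 == 0) return(NULL)
  cuts <- sort(unique(v))
  cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  best <- Inf; bestCut <- NA
  for (cc in cuts) {
    l <- a[v < cc]; r <- a[v >= cc]
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (sse < best - 1e-12) { best <- sse; bestCut <- cc }
  }
  if (1 - best / sse0 < gate) return(NULL)
  bestCut
}

# compact cohort for unit tests: planted linear signal, no batch/missingness
tinyCohortConfig <- function(n = 300, seed = 1) {
  simulationConfig(
    nPatients = n,
    modalities = c(CLIN = 10, CT = 15, PET = 15),
    nInformative = c(CLIN = 2, CT = 2, PET = 2),
    effectSize = 1.2,
    targetPrevalence = 0.2,
    batch = list(nBatches = 1, shift = 0, scale = 1,
                 modalities = c("CT", "PET")),
    missingness = NULL,
    seed = seed)
}
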
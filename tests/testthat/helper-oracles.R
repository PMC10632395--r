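# Independent brute-force oracles shared across test files.  These are
# written as plain double loops / direct formula transcriptions, kept
# deliberately separate from the package's vectorized implementations.

oracle_auroc <- function(scores, labels) {
  hi <- scores[labels == "high"]; lo <- scores[labels == "low"]
  tot <- 0
  for (a in hi) for (b in lo)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(hi) * length(lo))
}

oracle_cindex <- function(scores, times, events) {
  n <- length(scores); conc <- 0; comp <- 0L
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ta <- times[a]; tb <- times[b]; ea <- events[a]; eb <- events[b]
    short <- if (ta < tb && ea) a else if (tb < ta && eb) b
             else if (ta == tb && xor(ea == 1, eb == 1)) (if (ea) a else b)
             else next
    long <- if (short == a) b else a
    comp <- comp + 1L
    if (scores[short] > scores[long]) conc <- conc + 1
    else if (scores[short] == scores[long]) conc <- conc + 0.5
  }
  list(c = conc / comp, n_comp = comp)
}

# hand-coded DerSimonian-Laird, formula by formula
oracle_dl <- function(theta, se) {
  w <- 1 / se^2
  fe <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - fe)^2)
  k <- length(theta)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * theta) / sum(ws), se = sqrt(1 / sum(ws)),
       tau2 = tau2, q = q)
}
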
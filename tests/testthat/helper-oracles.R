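# Independent brute-force oracles. These must never call the package
# functions they are used to check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration over all
# integer tables with the observed margins.
oracle_fisher <- function(tbl) {
  a <- tbl[1, 1]
  r1 <- sum(tbl[1, ]); r2 <- sum(tbl[2, ]); c1 <- sum(tbl[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Direct evaluation of the BH step-up formula.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# AUC by direct pair counting, ties = 1/2.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (i in seq_along(sp)) {
    tot <- tot + sum(sp[i] > sn) + 0.5 * sum(sp[i] == sn)
  }
  tot / (length(sp) * length(sn))
}

# Youden J maximized by exhaustive scan over every cutpoint between distinct
# scores (rule: score > threshold -> positive); returns the maximum J.
oracle_youden_j <- function(scores, pos) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (thr in cand) {
    j <- mean(scores[pos] > thr) + mean(scores[!pos] <= thr) - 1
    best <- max(best, j)
  }
  best
}

# Global NNLS optimum by enumerating every active-set pattern (k <= 3):
# for each subset of columns solve unconstrained LS; feasible iff all
# coefficients >= 0; take the feasible subset with smallest objective.
oracle_nnls_objective <- function(X, y) {
  k <- ncol(X)
  best <- sum(y^2)  # w = 0
  for (size in seq_len(k)) {
    for (cols in utils::combn(k, size, simplify = FALSE)) {
      Xs <- X[, cols, drop = FALSE]
      fit <- tryCatch(qr.solve(crossprod(Xs), crossprod(Xs, y)),
                      error = function(e) NULL)
      if (is.null(fit) || any(fit < 0)) next
      best <- min(best, sum((y - Xs %*% fit)^2))
    }
  }
  best
}

# Product-limit estimate by hand: returns survival at each distinct event
# time (events precede censorings at tied times).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
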
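# Independent oracles used across the suite. Each recomputes the target
# quantity by a different route than the package (explicit set operations,
# scalar loops, dense closed forms, threshold sweeps) so agreement is
# evidence, not tautology.

# Jaccard similarity via explicit index sets, pair by pair.
oracleJaccard <- function(M) {
  n <- nrow(M)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- which(M[i, ] == 1); sj <- which(M[j, ] == 1)
    u <- length(union(si, sj))
    out[i, j] <- if (u == 0) 0 else length(intersect(si, sj)) / u
  }
  out
}

# Dense closed-form normalized adjacency D^(-1/2) (A + I) D^(-1/2).
oracleNormAdj <- function(pairs, n) {
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(pairs))) {
    A[pairs$i[r], pairs$j[r]] <- 1
    A[pairs$j[r], pairs$i[r]] <- 1
  }
  At <- A + diag(n)
  Dm <- diag(1 / sqrt(rowSums(At)))
  Dm %*% At %*% Dm
}

# Attention fusion recomputed scalar-by-scalar per drug.
oracleAttention <- function(Z, H, params) {
  n <- nrow(Z)
  attZ <- attH <- numeric(n)
  E <- matrix(0, n, ncol(Z))
  for (i in seq_len(n)) {
    uz <- tanh(params$attW %*% Z[i, ] + params$attB)
    uh <- tanh(params$attW %*% H[i, ] + params$attB)
    sz <- sum(params$attQ * uz); sh <- sum(params$attQ * uh)
    attZ[i] <- exp(sz) / (exp(sz) + exp(sh))
    attH[i] <- exp(sh) / (exp(sz) + exp(sh))
    E[i, ] <- attZ[i] * Z[i, ] + attH[i] * H[i, ]
  }
  list(E = E, attZ = attZ, attH = attH)
}

# Plain multilayer GCN forward, coded independently of fuseForward.
oracleGCNForward <- function(X, Ahat, Wg) {
  Z <- X
  for (l in seq_along(Wg)) {
    pre <- as.matrix(Ahat %*% Z) %*% Wg[[l]]
    Z <- ifelse(pre > 0, pre, 0)
  }
  Z
}

# Metric bundle by explicit confusion-matrix counting and threshold sweeps.
oracleMetrics <- function(probs, labels) {
  n <- nrow(probs); C <- ncol(probs)
  pred <- integer(n)
  for (r in seq_len(n)) pred[r] <- which.max(probs[r, ])
  acc <- sum(pred == labels) / n
  sc <- as.numeric(probs)
  y <- numeric(n * C)
  for (r in seq_len(n)) y[(labels[r] - 1) * n + r] <- 1
  # ROC by sweeping every distinct threshold, trapezoidal area
  th <- sort(unique(sc), decreasing = TRUE)
  tpr <- fpr <- numeric(length(th) + 1)
  nP <- sum(y == 1); nN <- sum(y == 0)
  for (k in seq_along(th)) {
    tpr[k + 1] <- sum(sc >= th[k] & y == 1) / nP
    fpr[k + 1] <- sum(sc >= th[k] & y == 0) / nN
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  # average precision: sum over thresholds of (delta recall) * precision
  ap <- 0; prevRec <- 0
  for (k in seq_along(th)) {
    sel <- sc >= th[k]
    prec <- sum(sel & y == 1) / sum(sel)
    rec <- sum(sel & y == 1) / nP
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  pres <- recs <- f1s <- c()
  for (cl in sort(unique(labels))) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    pres <- c(pres, p); recs <- c(recs, r)
    f1s <- c(f1s, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  list(acc = acc, aucMicro = auc, auprMicro = ap,
       preMacro = mean(pres), recallMacro = mean(recs),
       f1Macro = mean(f1s))
}

# Random binary descriptor matrix.
randomBits <- function(n, d, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.double(runif(n * d) < p), n, d)
}

# Small labeled dataset for training toys: nDrugs drugs on a path-ish
# graph with classes assigned per pair.
toyEvents <- function(nDrugs, nPairs, nClasses, seed = 1) {
  set.seed(seed)
  all <- which(upper.tri(matrix(0, nDrugs, nDrugs)), arr.ind = TRUE)
  pick <- sample(nrow(all), min(nPairs, nrow(all)))
  data.frame(i = all[pick, 1], j = all[pick, 2],
             class = sample(nClasses, length(pick), replace = TRUE))
}

# Random row-stochastic probability matrix.
randomProbs <- function(n, C) {
  m <- matrix(stats::rexp(n * C), n, C)
  m / rowSums(m)
}
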
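# Pair-vector dimension for a combiner over d-dimensional embeddings.
pairDim <- function(combiner, d) {
  switch(combiner,
    average = , hadamard = , l1 = d,
    concatenation = 2L * d,
    stop("unknown combiner '", combiner,
         "'; valid options: average, hadamard, l1, concatenation"))
}

#' Combine two drug embeddings into a pair vector
#'
#' The four standard link-prediction combiners: `average`
#' `(phi_i + phi_j)/2`, `hadamard` (elementwise product), `l1`
#' (elementwise absolute difference) and `concatenation` (dimension 2d;
#' applied in canonical order `i < j` so it is deterministic for an
#' unordered pair).
#'
#' @param E embedding matrix (`n x d`) or a [FusedEmbedding-class].
#' @param pairs `data.frame` with integer columns `i`, `j` (`i != j`).
#' @param combiner one of `"average"`, `"hadamard"`, `"l1"`,
#'   `"concatenation"`.
#' @return matrix with one row per pair (`d` or `2d` columns).
#' @export
combinePairs <- function(E, pairs, combiner = "average") {
  if (methods::is(E, "FusedEmbedding")) E <- E@E
  pairDim(combiner, ncol(E))  # validates the combiner label
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  if (any(i == j)) stop("pair with i == j is not a drug pair")
  if (any(c(i, j) < 1L) || any(c(i, j) > nrow(E)))
    stop("pair index out of range")
  if (combiner == "concatenation") {
    lo <- pmin(i, j); hi <- pmax(i, j)
    return(cbind(E[lo, , drop = FALSE], E[hi, , drop = FALSE]))
  }
  Ei <- E[i, , drop = FALSE]; Ej <- E[j, , drop = FALSE]
  switch(combiner,
    average = (Ei + Ej) / 2,
    hadamard = Ei * Ej,
    l1 = abs(Ei - Ej))
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Class probabilities for pair vectors
#'
#' A single affine map to C logits followed by a row-wise softmax; with no
#' head (`params$Wc` absent) the pair vectors are softmaxed directly,
#' which requires their dimension to equal C.
#'
#' @param P pair-vector matrix (`n_pairs x d` or `2d`).
#' @param params parameter list (uses `Wc`, `bc` when present).
#' @return `n_pairs x C` matrix of probabilities, rows summing to 1.
#' @export
classifyPairs <- function(P, params) {
  if (!is.null(params$Wc)) {
    if (ncol(P) != nrow(params$Wc))
      stop(sprintf("pair-vector dimension %d does not match classifier input %d",
                   ncol(P), nrow(params$Wc)))
    logits <- sweep(P %*% params$Wc, 2, params$bc, `+`)
  } else logits <- P
  softmaxRows(logits)
}

#' Mean multiclass cross-entropy
#'
#' `-mean(log p(true class))` over pairs. Zero probabilities at a true
#' class are clamped at `1e-12` (with a message) to keep the loss finite.
#'
#' @param probs `n x C` probability matrix, rows summing to 1.
#' @param labels integer class labels in `1..C`.
#' @return nonnegative scalar.
#' @export
crossEntropy <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels)]
  if (any(p <= 0)) {
    message(sum(p <= 0), " zero probability(ies) at true classes clamped to 1e-12")
    p <- pmax(p, 1e-12)
  }
  -mean(log(p))
}

# Accumulate row-block gradients: adds V's rows into rows idx of an
# n x d zero matrix (idx may repeat).
accumRows <- function(n, idx, V) {
  g <- rowsum(V, idx)
  out <- matrix(0, n, ncol(V))
  out[as.integer(rownames(g)), ] <- g
  out
}

# Backpropagate the classifier + combiner to the embedding gradient dE.
combinerBackward <- function(E, pairs, combiner, dP) {
  n <- nrow(E)
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  if (combiner == "concatenation") {
    lo <- pmin(i, j); hi <- pmax(i, j)
    d <- ncol(E)
    return(accumRows(n, lo, dP[, 1:d, drop = FALSE]) +
           accumRows(n, hi, dP[, (d + 1):(2 * d), drop = FALSE]))
  }
  Ei <- E[i, , drop = FALSE]; Ej <- E[j, , drop = FALSE]
  switch(combiner,
    average = accumRows(n, i, dP / 2) + accumRows(n, j, dP / 2),
    hadamard = accumRows(n, i, dP * Ej) + accumRows(n, j, dP * Ei),
    l1 = {
      s <- sign(Ei - Ej)
      accumRows(n, i, dP * s) + accumRows(n, j, -dP * s)
    })
}

# Full loss and analytic gradients of every parameter. `target` is the
# reconstruction target (NULL disables the reconstruction term). Returns
# list(loss, ce, rec, grads) with grads mirroring the params structure.
fusionGrad <- function(X, Ahat, params, config, pairs, labels,
                       combiner, target = NULL) {
  fw <- fuseForward(X, Ahat, params, config, keepCache = TRUE)
  emb <- fw$emb; cache <- fw$cache
  L <- length(config$layerDims)
  n <- nrow(emb@E)
  np <- nrow(pairs)
  variant <- config$variant

  P <- combinePairs(emb@E, pairs, combiner)
  probs <- classifyPairs(P, params)
  ce <- crossEntropy(probs, labels)
  Y <- matrix(0, np, ncol(probs))
  Y[cbind(seq_len(np), labels)] <- 1
  dlogits <- (probs - Y) / np
  g <- list()
  if (!is.null(params$Wc)) {
    g$Wc <- crossprod(P, dlogits)
    g$bc <- colSums(dlogits)
    dP <- dlogits %*% t(params$Wc)
  } else dP <- dlogits
  dE <- combinerBackward(emb@E, pairs, combiner, dP)

  ZL <- cache$Z[[L + 1]]; HL <- cache$H[[L + 1]]
  rec <- 0
  dHL_rec <- NULL
  if (cache$useAE && config$reconWeight > 0 && !is.null(target)) {
    R <- sigmoid(tcrossprod(HL))
    rec <- mean((R - target)^2)
    G <- (2 * config$reconWeight / n^2) * (R - target) * R * (1 - R)
    dHL_rec <- (G + t(G)) %*% HL
  }

  if (variant %in% c("full", "no_delivery")) {
    az <- attScores(ZL, params$attW, params$attB, params$attQ)
    wh <- if (is.null(params$attW2)) params$attW else params$attW2
    bh <- if (is.null(params$attB2)) params$attB else params$attB2
    ah <- attScores(HL, wh, bh, params$attQ)
    m <- pmax(az$s, ah$s)
    ez <- exp(az$s - m); eh <- exp(ah$s - m)
    attZ <- ez / (ez + eh); attH <- eh / (ez + eh)
    dZ <- dE * attZ
    dH <- dE * attH
    ds <- attZ * attH * (rowSums(dE * ZL) - rowSums(dE * HL))
    dUz <- outer(ds, params$attQ) * (1 - az$U^2)
    dUh <- outer(-ds, params$attQ) * (1 - ah$U^2)
    g$attQ <- as.numeric(crossprod(az$U, ds) - crossprod(ah$U, ds))
    if (is.null(params$attW2)) {
      g$attW <- crossprod(dUz, ZL) + crossprod(dUh, HL)
      g$attB <- colSums(dUz) + colSums(dUh)
    } else {
      g$attW <- crossprod(dUz, ZL); g$attB <- colSums(dUz)
      g$attW2 <- crossprod(dUh, HL); g$attB2 <- colSums(dUh)
    }
    dZ <- dZ + dUz %*% params$attW
    dH <- dH + dUh %*% wh
  } else if (variant == "no_att") {
    dZ <- dE; dH <- dE
  } else if (variant == "no_ae") {
    dZ <- dE; dH <- NULL
  } else { # no_gcn
    dZ <- NULL; dH <- dE
  }
  if (!is.null(dHL_rec)) dH <- if (is.null(dH)) dHL_rec else dH + dHL_rec

  g$We <- vector("list", L); g$be <- vector("list", L)
  g$Wg <- vector("list", L)
  alpha <- cache$alpha
  for (l in L:1) {
    dZprev <- NULL; dHdeliv <- NULL
    if (cache$useGCN) {
      dpreZ <- dZ * (cache$preZ[[l]] > 0)
      M <- as.matrix(Ahat %*% cache$Zt[[l]])
      g$Wg[[l]] <- crossprod(M, dpreZ)
      dZt <- as.matrix(Ahat %*% (dpreZ %*% t(params$Wg[[l]])))
      if (l > 1) {
        dZprev <- (1 - alpha) * dZt
        if (cache$useAE && alpha > 0) dHdeliv <- alpha * dZt
      }
    }
    dHprev <- NULL
    if (cache$useAE) {
      dpreH <- dH * (cache$preH[[l]] > 0)
      g$We[[l]] <- crossprod(cache$H[[l]], dpreH)
      g$be[[l]] <- colSums(dpreH)
      if (l > 1) dHprev <- dpreH %*% t(params$We[[l]])
    }
    if (l > 1) {
      dZ <- dZprev
      dH <- dHprev
      if (!is.null(dHdeliv))
        dH <- if (is.null(dH)) dHdeliv else dH + dHdeliv
    }
  }
  # zero gradients for parameters untouched by the variant, so the Adam
  # update stays structurally aligned
  zeroLike <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  for (nm in names(params)) {
    if (nm %in% c("We", "be", "Wg")) {
      if (is.null(g[[nm]])) g[[nm]] <- lapply(params[[nm]], zeroLike)
      else for (l in seq_len(L))
        if (is.null(g[[nm]][[l]])) g[[nm]][[l]] <- zeroLike(params[[nm]][[l]])
    } else if (is.null(g[[nm]])) g[[nm]] <- zeroLike(params[[nm]])
  }
  g <- g[names(params)]  # align structure with params for the optimizer
  list(loss = ce + (if (cache$useAE) config$reconWeight * rec else 0),
       ce = ce, rec = rec, grads = g)
}

# Elementwise recursion over parallel parameter structures.
structMap <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(k)
      do.call(structMap, c(list(f), lapply(args, `[[`, k))))
    names(out) <- names(args[[1]])
    out
  } else do.call(f, args)
}

adamInit <- function(params)
  list(m = structMap(function(x) x * 0, params),
       v = structMap(function(x) x * 0, params), t = 0L)

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- structMap(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- structMap(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  params <- structMap(function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v)
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param combiner pair combiner (default `"average"`, the best-performing
#'   choice in the model's sensitivity analysis).
#' @param learningRate Adam learning rate (default 0.003).
#' @param batchSize minibatch size in pairs (default 128); each epoch is
#'   one shuffled pass over the training pairs.
#' @param maxEpochs maximum epochs (default 1000).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 20); best-epoch parameters are restored.
#' @param validationFraction fraction of training pairs held out to
#'   monitor validation cross-entropy (default 0.1).
#' @param monitor early-stopping quantity: `"macroCE"` (default;
#'   class-balanced validation cross-entropy, the mean over classes of the
#'   per-class mean CE — robust to the long-tailed class prior) or
#'   `"meanCE"` (plain validation cross-entropy).
#' @param head `"affine"` (one linear layer + softmax) or `"none"`
#'   (softmax the pair vector directly; requires pair dimension C).
#' @param seed integer seed governing the validation split.
#' @return named list (class `"trainConfig"`).
#' @export
trainConfig <- function(combiner = "average", learningRate = 0.003,
                        batchSize = 128L, maxEpochs = 1000L, patience = 20L,
                        validationFraction = 0.1,
                        monitor = c("macroCE", "meanCE"),
                        head = c("affine", "none"), seed = 1L) {
  head <- match.arg(head)
  monitor <- match.arg(monitor)
  stopifnot(learningRate > 0, batchSize >= 1, patience >= 1, maxEpochs >= 1,
            validationFraction >= 0, validationFraction < 1)
  pairDim(combiner, 1L)  # validates the label
  structure(list(combiner = combiner, learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 validationFraction = validationFraction,
                 monitor = monitor, head = head,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Train the fusion model end to end
#'
#' Joint minimization of `cross-entropy + lambda * reconstruction` with
#' full-batch Adam. A fraction of the training pairs is held out to
#' monitor validation cross-entropy; training stops once no improvement
#' is seen for `patience` epochs and the best-epoch parameters are
#' restored. Fully deterministic given the seeds in the two configs.
#'
#' The adjacency passed in must be built from training pairs only (see
#' [buildAdjacency()]'s `edgeSubset`), otherwise held-out edges leak
#' through the topology channel.
#'
#' @param features a [DrugFeatureTable-class] (or plain matrix X).
#' @param Ahat normalized adjacency over training edges.
#' @param pairs training `data.frame` with columns `i`, `j`, `class`.
#' @param modelCfg a [fusionConfig()]; its last layer width must equal the
#'   number of classes.
#' @param trainCfg a [trainConfig()].
#' @param target reconstruction target; default: the mean per-view
#'   similarity matrix when `features` is a [DrugFeatureTable-class].
#' @return a [FusionFit-class].
#' @export
trainFusionModel <- function(features, Ahat, pairs,
                             modelCfg = fusionConfig(),
                             trainCfg = trainConfig(),
                             target = NULL) {
  isTable <- methods::is(features, "DrugFeatureTable")
  X <- if (isTable) features@X else unname(as.matrix(features))
  ids <- if (isTable) features@drugIds else paste0("drug_", seq_len(nrow(X)))
  if (is.null(target) && isTable && modelCfg$reconWeight > 0 &&
      modelCfg$variant != "no_ae")
    target <- similarityTarget(features)
  C <- modelCfg$layerDims[length(modelCfg$layerDims)]
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("i", "j", "class") %in% names(pairs)),
            all(pairs$class >= 1L), all(pairs$class <= C))

  params <- initFusionParams(modelCfg, ncol(X), combiner = trainCfg$combiner,
                             head = trainCfg$head)
  set.seed(trainCfg$seed)
  # stratified validation split: every class with at least two training
  # pairs contributes, so the class-balanced monitor sees the tail classes
  vidx <- if (trainCfg$validationFraction > 0) {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$class), function(ix) {
      if (length(ix) < 2) return(integer())
      sample(ix, max(1L, floor(trainCfg$validationFraction * length(ix))))
    }), use.names = FALSE)
  } else integer()
  trainPairs <- if (length(vidx)) pairs[-vidx, , drop = FALSE] else pairs
  valPairs <- pairs[vidx, , drop = FALSE]

  state <- adamInit(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", trainCfg$maxEpochs)
  wait <- 0L
  nTr <- nrow(trainPairs)
  for (epoch in seq_len(trainCfg$maxEpochs)) {
    perm <- sample(nTr)
    starts <- seq(1L, nTr, by = trainCfg$batchSize)
    epLoss <- epCE <- epRec <- 0
    for (s in starts) {
      idx <- perm[s:min(s + trainCfg$batchSize - 1L, nTr)]
      batch <- trainPairs[idx, , drop = FALSE]
      res <- fusionGrad(X, Ahat, params, modelCfg, batch,
                        batch$class, trainCfg$combiner, target)
      if (!is.finite(res$loss))
        stop(sprintf("training diverged at epoch %d (loss %g); try a lower learning rate",
                     epoch, res$loss))
      up <- adamStep(params, res$grads, state, trainCfg$learningRate)
      params <- up$params; state <- up$state
      w <- length(idx) / nTr
      epLoss <- epLoss + w * res$loss
      epCE <- epCE + w * res$ce
      epRec <- epRec + w * res$rec
    }
    res <- list(loss = epLoss, ce = epCE, rec = epRec)
    if (nrow(valPairs)) {
      emb <- fuseForward(X, Ahat, params, modelCfg)
      pv <- classifyPairs(
        combinePairs(emb@E, valPairs, trainCfg$combiner), params)
      ceRows <- -log(pmax(pv[cbind(seq_len(nrow(valPairs)),
                                   valPairs$class)], 1e-12))
      valMean <- mean(ceRows)
      valMacro <- mean(tapply(ceRows, valPairs$class, mean))
    } else valMean <- valMacro <- res$ce
    valCE <- if (trainCfg$monitor == "macroCE") valMacro else valMean
    hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = res$loss,
                                trainCE = res$ce, recon = res$rec,
                                valMeanCE = valMean, valCE = valCE)
    if (valCE < best$val - 1e-9) {
      best <- list(val = valCE, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= trainCfg$patience) break
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  cfg <- c(unclass(modelCfg), unclass(trainCfg)[setdiff(names(trainCfg), "seed")],
           list(trainSeed = trainCfg$seed, bestEpoch = best$epoch))
  new("FusionFit", params = best$params, config = cfg, history = history,
      drugIds = as.character(ids), nClasses = as.integer(C))
}

# Rebuild a fusionConfig from a FusionFit's stored snapshot.
fitModelConfig <- function(fit) {
  cfg <- fit@config
  fusionConfig(layerDims = cfg$layerDims, alpha = cfg$alpha,
               reconWeight = cfg$reconWeight, attentionDim = cfg$attentionDim,
               sharedAttention = cfg$sharedAttention, variant = cfg$variant,
               seed = cfg$seed)
}

#' Predict event classes for drug pairs
#'
#' Runs the forward pass with the fitted parameters, builds pair vectors
#' with the training combiner and returns per-pair class probabilities
#' with the top-scoring class, ranked by descending score. Ties are broken
#' lexicographically by `(i, j, class)` so reports are reproducible. Pairs
#' need not have been seen in training.
#'
#' @param fit a [FusionFit-class].
#' @param features feature table or matrix X (same drug order as training).
#' @param Ahat inference adjacency (training edges; unseen drugs appear as
#'   self-loop-only nodes).
#' @param pairs `data.frame` with columns `i`, `j`.
#' @return `data.frame` (i, j, class, score) sorted by descending score,
#'   with the full probability matrix in `attr(, "probs")` and the fused
#'   embedding in `attr(, "embedding")`.
#' @export
predictEvents <- function(fit, features, Ahat, pairs) {
  X <- if (methods::is(features, "DrugFeatureTable")) features@X
       else unname(as.matrix(features))
  pairs <- as.data.frame(pairs)
  if (any(pairs$i < 1L | pairs$j < 1L |
          pairs$i > nrow(X) | pairs$j > nrow(X)))
    stop("unknown drug index in prediction pairs")
  emb <- fuseForward(X, Ahat, fit@params, fitModelConfig(fit))
  P <- combinePairs(emb@E, pairs, fit@config$combiner)
  probs <- classifyPairs(P, fit@params)
  cls <- max.col(probs, ties.method = "first")
  score <- probs[cbind(seq_len(nrow(probs)), cls)]
  out <- data.frame(i = pairs$i, j = pairs$j, class = cls, score = score)
  ord <- order(-out$score, out$i, out$j, out$class)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "probs") <- probs[ord, , drop = FALSE]
  attr(out, "embedding") <- emb
  out
}

#' Save / load a fitted model
#'
#' The checkpoint is a single file holding every parameter array plus the
#' resolved configuration; `readFusionFit(saveFusionFit(fit, f))`
#' round-trips bit-exactly. The configuration is additionally written as
#' JSON next to the checkpoint for human inspection.
#'
#' @param fit a [FusionFit-class].
#' @param path checkpoint file path.
#' @return `saveFusionFit` returns `path` invisibly; `readFusionFit`
#'   returns the [FusionFit-class].
#' @export
saveFusionFit <- function(fit, path) {
  saveRDS(fit, path)
  cfgPath <- paste0(path, ".config.json")
  jsonlite::write_json(fit@config[!vapply(fit@config, is.function, logical(1))],
                       cfgPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveFusionFit
#' @export
readFusionFit <- function(path) {
  fit <- readRDS(path)
  stopifnot(methods::is(fit, "FusionFit"))
  fit
}
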
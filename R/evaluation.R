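eventsOf <- function(x) if (methods::is(x, "DDIDataset")) eventTable(x) else as.data.frame(x)

#' Architecture scaled to a dataset
#'
#' The full-scale default architecture (`{2000, 256, 65}`) suits the
#' 572-drug / 65-class regime; for smaller problems this helper returns a
#' proportionally narrow stack `{64, 32, C}` with the final width tied to
#' the dataset's class count.
#'
#' @param dataset a [DDIDataset-class].
#' @param ... further arguments passed to [fusionConfig()] (e.g. `alpha`,
#'   `seed`, `variant`).
#' @return a [fusionConfig()].
#' @export
scaledFusionConfig <- function(dataset, ...) {
  fusionConfig(layerDims = c(64L, 32L, dataset@nClasses), ...)
}

#' Stratified fivefold split of interaction pairs
#'
#' Partitions the labeled pairs into `nFolds` disjoint test folds
#' (every pair in exactly one). Folds are stratified by event class when a
#' class has at least `nFolds` members, so rare classes appear in every
#' fold where possible; smaller classes are assigned at random with a
#' warning.
#'
#' @param events a [DDIDataset-class] or pair `data.frame` (i, j, class).
#' @param nFolds number of folds (default 5).
#' @param seed integer seed.
#' @param stratify stratify folds by event class (default TRUE).
#' @return list of `nFolds` elements, each `list(train =, test =)` pair
#'   `data.frame`s.
#' @export
splitPairs <- function(events, nFolds = 5L, seed = 1L, stratify = TRUE) {
  ev <- eventsOf(events)
  set.seed(seed)
  fold <- integer(nrow(ev))
  if (stratify) {
    # shuffle within class, then deal folds in one round-robin cycle that
    # continues across classes: folds stay balanced overall (sizes differ
    # by at most one) while every class spreads over consecutive folds
    nSmall <- 0L
    cursor <- sample(nFolds, 1L) - 1L
    for (cl in sort(unique(ev$class))) {
      idx <- which(ev$class == cl)
      idx <- idx[sample.int(length(idx))]   # safe for singleton classes
      if (length(idx) < nFolds) nSmall <- nSmall + length(idx)
      fold[idx] <- (cursor + seq_along(idx) - 1L) %% nFolds + 1L
      cursor <- cursor + length(idx)
    }
    if (nSmall > 0)
      warning(sprintf("%d pair(s) in classes smaller than %d folds assigned without stratification",
                      nSmall, nFolds))
  } else {
    fold <- sample(rep_len(seq_len(nFolds), nrow(ev)))
  }
  lapply(seq_len(nFolds), function(k)
    list(train = ev[fold != k, , drop = FALSE],
         test = ev[fold == k, , drop = FALSE]))
}

#' Drug-wise cold-start split (Tasks A and B)
#'
#' Splits the drugs (not the pairs) into known and new: a fraction
#' (default 20%) of drugs is held out to simulate drugs without any known
#' interaction. Training pairs have both drugs known; Task A test pairs
#' have exactly one new drug; Task B test pairs have both drugs new. The
#' three sets are mutually disjoint and no training pair touches a new
#' drug.
#'
#' @param events a [DDIDataset-class] or pair `data.frame`.
#' @param nDrugs total drug count (inferred from a dataset).
#' @param testFraction fraction of drugs held out (default 0.2; rounded up,
#'   e.g. 572 drugs give 115 new drugs).
#' @param seed integer seed.
#' @return list with `trainDrugs`, `testDrugs`, `train`, `testA`, `testB`.
#' @export
splitDrugs <- function(events, nDrugs = NULL, testFraction = 0.2, seed = 1L) {
  if (methods::is(events, "DDIDataset") && is.null(nDrugs))
    nDrugs <- nDrugs(events)
  ev <- eventsOf(events)
  stopifnot(!is.null(nDrugs), testFraction > 0, testFraction < 1)
  set.seed(seed)
  testDrugs <- sort(sample(nDrugs, ceiling(testFraction * nDrugs)))
  isTest <- seq_len(nDrugs) %in% testDrugs
  nNew <- isTest[ev$i] + isTest[ev$j]
  out <- list(trainDrugs = setdiff(seq_len(nDrugs), testDrugs),
              testDrugs = testDrugs,
              train = ev[nNew == 0L, , drop = FALSE],
              testA = ev[nNew == 1L, , drop = FALSE],
              testB = ev[nNew == 2L, , drop = FALSE])
  if (nrow(out$testA) == 0 && nrow(out$testB) == 0)
    stop("drug-wise split produced no test pairs; try another seed")
  out
}

#' Restrict a dataset to its k most frequent event classes
#'
#' Ranks classes by descending frequency (ties broken by the original
#' class id) and keeps only pairs of the top `k`; retained classes are
#' re-indexed `1..k` preserving rank order.
#'
#' @param events a [DDIDataset-class] or pair `data.frame`.
#' @param k number of classes to keep.
#' @return object of the same type with classes relabeled `1..k`.
#' @export
classSubset <- function(events, k) {
  if (k < 1) stop("k must be at least 1")
  isDataset <- methods::is(events, "DDIDataset")
  ev <- eventsOf(events)
  counts <- table(factor(ev$class))
  rankOrder <- as.integer(names(counts)[order(-as.integer(counts),
                                              as.integer(names(counts)))])
  keep <- rankOrder[seq_len(min(k, length(rankOrder)))]
  relabel <- setNames(seq_along(keep), keep)
  sub <- ev[ev$class %in% keep, , drop = FALSE]
  sub$class <- as.integer(relabel[as.character(sub$class)])
  rownames(sub) <- NULL
  if (!isDataset) return(sub)
  new("DDIDataset", views = events@views, events = sub,
      nClasses = as.integer(length(keep)), drugIds = events@drugIds,
      communities = events@communities)
}

# Wilcoxon/rank AUC for a binary vector y against scores (ties by average
# rank, equivalent to the trapezoidal ROC area).
rankAUC <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Average precision with tied scores processed as blocks.
averagePrecision <- function(scores, y) {
  nPos <- sum(y == 1)
  if (nPos == 0) return(NA_real_)
  ord <- order(-scores)
  y <- y[ord]; s <- scores[ord]
  block <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(block, fromLast = TRUE)  # end of each tie block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  dtp <- diff(c(0, tp))
  sum(dtp * prec) / nPos
}

#' Multiclass metric bundle
#'
#' ACC (argmax accuracy), micro-averaged AUPR and AUC computed on the
#' flattened one-vs-rest binarized label/score matrix, and macro-averaged
#' precision, recall and F1 as unweighted means over the classes present
#' in the test labels (absent classes are excluded with a message). A
#' predicted class with no predictions contributes precision 0; a class
#' with no true members is excluded.
#'
#' @param probs `n_pairs x C` probability matrix, rows summing to 1.
#' @param labels integer true classes in `1..C`.
#' @return list with `acc`, `auprMicro`, `aucMicro`, `f1Macro`,
#'   `preMacro`, `recallMacro`, a `perClass` `data.frame` and
#'   `nTestPairs`.
#' @export
computeMetrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  n <- nrow(probs); C <- ncol(probs)
  stopifnot(length(labels) == n, all(labels >= 1), all(labels <= C))
  pred <- max.col(probs, ties.method = "first")
  acc <- mean(pred == labels)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), labels)] <- 1
  aucMicro <- rankAUC(as.numeric(probs), as.numeric(Y))
  auprMicro <- averagePrecision(as.numeric(probs), as.numeric(Y))
  present <- sort(unique(labels))
  if (length(present) < C)
    message(C - length(present),
            " class(es) absent from the test labels excluded from macro averages")
  perClass <- do.call(rbind, lapply(present, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    data.frame(class = cl, support = tp + fn, precision = pre,
               recall = rec, f1 = f1)
  }))
  list(acc = acc, auprMicro = auprMicro, aucMicro = aucMicro,
       f1Macro = mean(perClass$f1), preMacro = mean(perClass$precision),
       recallMacro = mean(perClass$recall), perClass = perClass,
       nTestPairs = n)
}

#' Macro-F1 of the best constant prediction (chance level)
#'
#' The chance level implied by a class prior: always predicting the
#' majority class gives that class F1 `2p/(1+p)` and every other class 0;
#' the macro mean over the classes present is the floor a signal-free
#' model should not exceed by much.
#'
#' @param labels integer class labels.
#' @return scalar chance-level macro-F1.
#' @export
chanceMacroF1 <- function(labels) {
  tab <- table(labels)
  p <- max(tab) / length(labels)
  (2 * p / (1 + p)) / length(tab)
}

# Fit + score one train/test split. Returns metrics plus the fit and the
# fused training embedding.
fitAndScore <- function(features, trainPairs, testPairs, nDrugs,
                        modelCfg, trainCfg, allEvents = NULL) {
  Ahat <- buildAdjacency(if (is.null(allEvents)) trainPairs else allEvents,
                         nDrugs = nDrugs, edgeSubset = trainPairs)
  fit <- trainFusionModel(features, Ahat, trainPairs, modelCfg, trainCfg)
  pr <- predictEvents(fit, features, Ahat, testPairs)
  probs <- attr(pr, "probs")
  key <- paste(pr$i, pr$j)
  m <- match(paste(testPairs$i, testPairs$j), key)
  metrics <- computeMetrics(probs[m, , drop = FALSE], testPairs$class)
  list(metrics = metrics, fit = fit,
       embedding = attr(pr, "embedding"), Ahat = Ahat)
}

#' Fivefold cross-validation over interaction pairs
#'
#' For each fold the adjacency is rebuilt from the training-fold pairs
#' only, the model is retrained, and the held-out pairs are scored.
#' The reported score is the mean over folds (standard deviations are
#' included).
#'
#' @param dataset a [DDIDataset-class].
#' @param modelCfg,trainCfg configurations (see [fusionConfig()],
#'   [trainConfig()]); `modelCfg = NULL` uses [scaledFusionConfig()].
#' @param nFolds number of folds (default 5).
#' @param seed split seed.
#' @return list with `folds` (per-fold metric lists), `mean` and `sd`
#'   (named numeric summaries).
#' @export
crossValidate <- function(dataset, modelCfg = NULL,
                          trainCfg = trainConfig(), nFolds = 5L, seed = 1L) {
  if (is.null(modelCfg)) modelCfg <- scaledFusionConfig(dataset, seed = seed)
  features <- buildFeatureTable(dataset)
  folds <- splitPairs(dataset, nFolds = nFolds, seed = seed)
  res <- lapply(folds, function(f)
    fitAndScore(features, f$train, f$test, nDrugs(dataset),
                modelCfg, trainCfg)$metrics)
  scalars <- c("acc", "auprMicro", "aucMicro", "f1Macro", "preMacro",
               "recallMacro")
  M <- sapply(scalars, function(s) vapply(res, `[[`, numeric(1), s))
  list(folds = res, mean = colMeans(M), sd = apply(M, 2, stats::sd))
}

#' Cold-start evaluation (Task A / Task B)
#'
#' Drug-wise 80/20 split; the model is trained on pairs between known
#' drugs with the inference adjacency containing training edges plus
#' self-loops for the new drugs (so their descriptor features still flow
#' through the delivery operation). Task A scores known-new pairs, Task B
#' new-new pairs.
#'
#' @param dataset a [DDIDataset-class].
#' @param mode `"task_a"` or `"task_b"`.
#' @param testFraction fraction of drugs held out (default 0.2).
#' @param modelCfg,trainCfg configurations.
#' @param seed split seed.
#' @return list with `metrics`, the `split`, and the `fit`.
#' @export
evaluateColdStart <- function(dataset, mode = c("task_a", "task_b"),
                              testFraction = 0.2,
                              modelCfg = NULL,
                              trainCfg = trainConfig(), seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(modelCfg)) modelCfg <- scaledFusionConfig(dataset, seed = seed)
  features <- buildFeatureTable(dataset)
  sp <- splitDrugs(dataset, testFraction = testFraction, seed = seed)
  testPairs <- if (mode == "task_a") sp$testA else sp$testB
  if (nrow(testPairs) == 0)
    stop("no test pairs for ", mode, "; try another seed")
  stopifnot(!any(sp$train$i %in% sp$testDrugs),
            !any(sp$train$j %in% sp$testDrugs))
  res <- fitAndScore(features, sp$train, testPairs, nDrugs(dataset),
                     modelCfg, trainCfg)
  list(metrics = res$metrics, split = sp, fit = res$fit)
}

#' Run one ablation variant
#'
#' Variants mirror the model's component knock-outs: `no_ae` removes the
#' feature channel and sets alpha = 0 (a plain multilayer GCN); `no_gcn`
#' uses the autoencoder embedding end to end; `no_att` replaces attention
#' by the sum of the two final embeddings; `no_delivery` sets alpha = 0
#' but keeps attention over the two channel outputs.
#'
#' @param dataset a [DDIDataset-class].
#' @param variant one of `"full"`, `"no_ae"`, `"no_gcn"`, `"no_att"`,
#'   `"no_delivery"`.
#' @param modelCfg base configuration (its `variant` field is overridden).
#' @param trainCfg training configuration.
#' @param split optional `list(train =, test =)` pair tables; default:
#'   fold 1 of a fivefold split under `seed`.
#' @param seed split seed.
#' @return list with `metrics`, `attention` (NULL for variants without
#'   attention coefficients), `variant` and the `fit`.
#' @export
runAblation <- function(dataset, variant = "full",
                        modelCfg = NULL, trainCfg = trainConfig(),
                        split = NULL, seed = 1L) {
  if (is.null(modelCfg)) modelCfg <- scaledFusionConfig(dataset, seed = seed)
  cfg <- modelCfg
  cfg$variant <- match.arg(variant, c("full", "no_ae", "no_gcn", "no_att",
                                      "no_delivery"))
  if (is.null(split)) split <- splitPairs(dataset, seed = seed)[[1]]
  features <- buildFeatureTable(dataset)
  res <- fitAndScore(features, split$train, split$test, nDrugs(dataset),
                     cfg, trainCfg)
  att <- if (cfg$variant %in% c("full", "no_delivery"))
    attentionReport(res$embedding, split$train) else NULL
  list(metrics = res$metrics, attention = att, variant = cfg$variant,
       fit = res$fit)
}

#' Attention-coefficient diagnostics
#'
#' Summarizes the per-drug attention split between the topology (Z) and
#' feature (H) channels: overall mean and standard deviation, and per
#' event class the mean coefficient over drugs incident to training edges
#' of that class.
#'
#' @param embedding a [FusedEmbedding-class].
#' @param events training pair `data.frame` (i, j, class) used for the
#'   per-class aggregation; omit for the overall summary only.
#' @return list with `meanAttZ`, `meanAttH`, `sdAttZ`, `sdAttH` and a
#'   `perClass` `data.frame` (when `events` is given).
#' @export
attentionReport <- function(embedding, events = NULL) {
  stopifnot(methods::is(embedding, "FusedEmbedding"))
  attZ <- embedding@attZ; attH <- embedding@attH
  out <- list(meanAttZ = mean(attZ), meanAttH = mean(attH),
              sdAttZ = stats::sd(attZ), sdAttH = stats::sd(attH))
  if (!is.null(events)) {
    ev <- eventsOf(events)
    out$perClass <- do.call(rbind, lapply(sort(unique(ev$class)), function(cl) {
      drugs <- unique(c(ev$i[ev$class == cl], ev$j[ev$class == cl]))
      data.frame(class = cl, nDrugs = length(drugs),
                 meanAttZ = mean(attZ[drugs]), meanAttH = mean(attH[drugs]))
    }))
  }
  out
}
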
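#' @import methods
#' @importFrom stats runif rnorm setNames
NULL

#' DDIDataset: binary descriptor views plus a labeled interaction table
#'
#' Container for one multitype drug-drug interaction dataset: one or more
#' binary drug-by-descriptor view matrices (e.g. chemical substructure,
#' target, enzyme) sharing a common drug ordering, and a table of labeled
#' interacting pairs. Event classes are integers in `1..nClasses`. Pairs are
#' stored canonically with `i < j`; an unordered pair appears at most once.
#'
#' @slot views named list of 0/1 matrices, one per feature view; all share
#'   `nrow` and row order (drugs).
#' @slot events `data.frame` with integer columns `i`, `j`, `class`
#'   (`i < j`, class in `1..nClasses`).
#' @slot nClasses integer, number of event classes C.
#' @slot drugIds character vector of unique drug identifiers, the shared row
#'   order of every view.
#' @slot communities integer vector of ground-truth community labels
#'   (synthetic data only; length 0 when unknown).
#'
#' @exportClass DDIDataset
setClass("DDIDataset",
  representation(
    views = "list",
    events = "data.frame",
    nClasses = "integer",
    drugIds = "character",
    communities = "integer"
  )
)

setValidity("DDIDataset", function(object) {
  msg <- character()
  n <- length(object@drugIds)
  if (anyDuplicated(object@drugIds))
    msg <- c(msg, "drugIds must be unique")
  if (length(object@views) < 1L)
    msg <- c(msg, "at least one descriptor view is required")
  for (v in seq_along(object@views)) {
    m <- object@views[[v]]
    if (!is.matrix(m) || nrow(m) != n)
      msg <- c(msg, sprintf("view %d must be a matrix with %d rows", v, n))
    else if (!all(m == 0 | m == 1))
      msg <- c(msg, sprintf("view %d has non-binary entries", v))
  }
  ev <- object@events
  if (nrow(ev) > 0) {
    if (!all(c("i", "j", "class") %in% names(ev)))
      msg <- c(msg, "events needs columns i, j, class")
    else {
      if (any(ev$i >= ev$j))
        msg <- c(msg, "event pairs must be canonical with i < j")
      if (any(ev$i < 1L | ev$j > n))
        msg <- c(msg, "event drug indices out of range")
      if (anyDuplicated(ev[, c("i", "j")]))
        msg <- c(msg, "duplicate unordered pairs in events")
      if (any(ev$class < 1L | ev$class > object@nClasses))
        msg <- c(msg, "event classes must lie in 1..nClasses")
    }
  }
  if (length(object@communities) &&
      length(object@communities) != n)
    msg <- c(msg, "communities must have one entry per drug")
  if (length(msg)) msg else TRUE
})

#' DrugFeatureTable: concatenated Jaccard-similarity feature matrix
#'
#' The model's node-feature input `X`: the column-wise concatenation of the
#' per-view drug-by-drug Jaccard similarity matrices, in a fixed recorded
#' view order, so `X` has shape `n_drugs x (n_views * n_drugs)`.
#'
#' @slot X numeric matrix, entries in `[0, 1]`.
#' @slot viewOffsets named list of integer column ranges, one per view.
#' @slot drugIds character row identifiers.
#'
#' @exportClass DrugFeatureTable
setClass("DrugFeatureTable",
  representation(X = "matrix", viewOffsets = "list", drugIds = "character")
)

setValidity("DrugFeatureTable", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@drugIds))
    msg <- c(msg, "X must have one row per drug id")
  if (any(object@X < 0 | object@X > 1))
    msg <- c(msg, "feature values must lie in [0, 1]")
  cols <- unlist(object@viewOffsets, use.names = FALSE)
  if (length(cols) != ncol(object@X) || anyDuplicated(cols))
    msg <- c(msg, "viewOffsets must partition the columns of X")
  if (length(msg)) msg else TRUE
})

#' FusedEmbedding: attention-fused drug representations
#'
#' Output of the fusion forward pass: the final embedding `E` together with
#' the last-layer channel embeddings and the per-drug attention
#' coefficients. For every drug `attZ + attH == 1`; `E` is the per-row
#' convex combination `attZ * Z + attH * H` (variants without attention
#' store degenerate coefficients).
#'
#' @slot E numeric matrix `n_drugs x C`, the fused embedding.
#' @slot Z numeric matrix, final topology-channel (GCN) embedding.
#' @slot H numeric matrix, final feature-channel (autoencoder) embedding.
#' @slot attZ,attH numeric per-drug attention coefficients.
#'
#' @exportClass FusedEmbedding
setClass("FusedEmbedding",
  representation(E = "matrix", Z = "matrix", H = "matrix",
                 attZ = "numeric", attH = "numeric")
)

#' FusionFit: a trained fusion model
#'
#' All learnable parameters of the feature channel, topology channel,
#' attention and classifier head, plus the resolved configuration snapshot
#' and per-epoch training history.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot config named list: the merged model/training configuration actually
#'   used (layer widths, alpha, combiner, learning rate, seed, variant, ...).
#' @slot history `data.frame` with one row per epoch (losses, validation
#'   cross-entropy).
#' @slot drugIds drug identifiers the model was trained over.
#' @slot nClasses number of event classes C.
#'
#' @exportClass FusionFit
setClass("FusionFit",
  representation(params = "list", config = "list", history = "data.frame",
                 drugIds = "character", nClasses = "integer")
)

setMethod("show", "DDIDataset", function(object) {
  cat(sprintf("DDIDataset: %d drugs, %d views (%s), %d labeled pairs, %d event classes\n",
              length(object@drugIds), length(object@views),
              paste(names(object@views), collapse = ", "),
              nrow(object@events), object@nClasses))
  if (length(object@communities))
    cat(sprintf("  ground-truth communities: %d\n",
                length(unique(object@communities))))
})

setMethod("show", "DrugFeatureTable", function(object) {
  cat(sprintf("DrugFeatureTable: %d drugs x %d columns (%d views: %s)\n",
              nrow(object@X), ncol(object@X), length(object@viewOffsets),
              paste(names(object@viewOffsets), collapse = ", ")))
})

setMethod("show", "FusedEmbedding", function(object) {
  cat(sprintf("FusedEmbedding: %d drugs x %d dims; mean attention Z=%.3f H=%.3f\n",
              nrow(object@E), ncol(object@E),
              mean(object@attZ), mean(object@attH)))
})

setMethod("show", "FusionFit", function(object) {
  cat(sprintf("FusionFit (%s): %d drugs, %d classes, layers {%s}, alpha=%.2f, combiner=%s\n",
              object@config$variant, length(object@drugIds), object@nClasses,
              paste(object@config$layerDims, collapse = ", "),
              object@config$alpha, object@config$combiner))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs (best %d, val CE %.4f)\n",
                nrow(object@history), object@config$bestEpoch,
                min(object@history$valCE, na.rm = TRUE)))
})
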
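#' Construct a DDIDataset
#'
#' Bundle binary descriptor view matrices and a labeled interaction table
#' into a validated [DDIDataset-class]. Pairs are canonicalized to `i < j`;
#' self-pairs are rejected and duplicate unordered pairs raise an error.
#'
#' @param views named list of 0/1 matrices (drugs x descriptors), all with
#'   the same number of rows and row order.
#' @param events `data.frame` with columns `i`, `j`, `class` (drug indices
#'   and 1-based event class).
#' @param nClasses number of event classes C; defaults to `max(events$class)`.
#' @param drugIds drug identifiers; defaults to rownames of the first view
#'   or `drug_1..drug_n`.
#' @param communities optional integer ground-truth community labels.
#' @return a [DDIDataset-class].
#' @export
#' @examples
#' v <- matrix(rbinom(40, 1, 0.3), nrow = 8,
#'             dimnames = list(paste0("d", 1:8), NULL))
#' ev <- data.frame(i = c(1, 2), j = c(2, 5), class = c(1, 2))
#' DDIDataset(list(sub = v), ev)
DDIDataset <- function(views, events, nClasses = NULL, drugIds = NULL,
                       communities = integer()) {
  if (is.null(names(views)))
    names(views) <- paste0("view", seq_along(views))
  views <- lapply(views, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(drugIds)) {
    drugIds <- rownames(views[[1]])
    if (is.null(drugIds)) drugIds <- paste0("drug_", seq_len(nrow(views[[1]])))
  }
  events <- canonicalizePairs(events, length(drugIds))
  if (is.null(nClasses)) nClasses <- max(events$class, 1L)
  new("DDIDataset", views = views, events = events,
      nClasses = as.integer(nClasses), drugIds = as.character(drugIds),
      communities = as.integer(communities))
}

# Canonicalize an interaction table: i < j, self-pairs rejected,
# duplicates (after unordering) rejected.
canonicalizePairs <- function(events, nDrugs) {
  events <- as.data.frame(events)
  stopifnot(all(c("i", "j", "class") %in% names(events)))
  i <- as.integer(events$i); j <- as.integer(events$j)
  cls <- as.integer(events$class)
  if (any(i == j))
    stop("self-pairs (i == j) are not valid interactions")
  if (any(i < 1L | j < 1L | i > nDrugs | j > nDrugs))
    stop("drug index out of range 1..", nDrugs)
  lo <- pmin(i, j); hi <- pmax(i, j)
  out <- data.frame(i = lo, j = hi, class = cls)
  if (anyDuplicated(out[, c("i", "j")]))
    stop("duplicate unordered pair(s) after canonicalization")
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard similarity matrix of a binary descriptor view
#'
#' For each pair of drugs, computes `|d_i intersect d_j| / |d_i union d_j|`
#' treating descriptor rows as bit sets. The result is symmetric with
#' entries in `[0, 1]` and a unit diagonal for any drug with at least one
#' set bit. A drug with an all-zero descriptor row carries no similarity
#' evidence: every pair involving it (including its own diagonal) is set to
#' 0 and a warning is emitted.
#'
#' @param values 0/1 matrix, drugs in rows, descriptors in columns.
#' @return symmetric `n x n` numeric similarity matrix.
#' @export
#' @examples
#' m <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
#' jaccardMatrix(m)  # off-diagonal 1/3
jaccardMatrix <- function(values) {
  values <- as.matrix(values)
  bad <- which(values != 0 & values != 1, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop(sprintf("non-binary descriptor entry at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  storage.mode(values) <- "double"
  inter <- tcrossprod(values)
  sizes <- rowSums(values)
  uni <- outer(sizes, sizes, `+`) - inter
  if (any(sizes == 0))
    warning(sprintf("%d drug(s) have all-zero descriptor rows; their similarities are set to 0",
                    sum(sizes == 0)))
  out <- ifelse(uni > 0, inter / uni, 0)
  dimnames(out) <- if (is.null(rownames(values))) NULL
                   else list(rownames(values), rownames(values))
  out
}

#' Concatenate per-view similarity matrices into the feature matrix X
#'
#' Column-wise concatenation of the per-view drug-by-drug similarity
#' matrices, in the given (recorded) view order, producing the model input
#' `X` of shape `n_drugs x (n_views * n_drugs)`.
#'
#' @param sims named list of `n x n` similarity matrices sharing drug order.
#' @param drugIds optional drug identifiers (defaults to rownames of the
#'   first view).
#' @return a [DrugFeatureTable-class].
#' @export
concatFeatures <- function(sims, drugIds = NULL) {
  stopifnot(length(sims) >= 1)
  if (is.null(names(sims))) names(sims) <- paste0("view", seq_along(sims))
  n <- nrow(sims[[1]])
  for (v in seq_along(sims)) {
    m <- sims[[v]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop(sprintf("view '%s' is not an %d x %d matrix (shape/order mismatch)",
                   names(sims)[v], n, n))
  }
  if (is.null(drugIds)) {
    drugIds <- rownames(sims[[1]])
    if (is.null(drugIds)) drugIds <- paste0("drug_", seq_len(n))
  }
  X <- do.call(cbind, lapply(sims, unname))
  offsets <- lapply(seq_along(sims), function(v) ((v - 1L) * n + 1L):(v * n))
  names(offsets) <- names(sims)
  new("DrugFeatureTable", X = X, viewOffsets = offsets,
      drugIds = as.character(drugIds))
}

#' Build the concatenated Jaccard feature table of a dataset
#'
#' Convenience wrapper: Jaccard similarity per view, then concatenation.
#'
#' @param dataset a [DDIDataset-class].
#' @return a [DrugFeatureTable-class].
#' @export
buildFeatureTable <- function(dataset) {
  sims <- lapply(featureViews(dataset), jaccardMatrix)
  concatFeatures(sims, drugIds = drugIds(dataset))
}

#' Mean per-view similarity matrix (reconstruction target)
#'
#' The inner-product decoder of the feature channel reconstructs the
#' element-wise mean of the per-view Jaccard similarity matrices.
#'
#' @param features a [DrugFeatureTable-class].
#' @return symmetric `n x n` matrix in `[0, 1]`.
#' @export
similarityTarget <- function(features) {
  blocks <- lapply(features@viewOffsets, function(cols)
    features@X[, cols, drop = FALSE])
  Reduce(`+`, blocks) / length(blocks)
}

#' Symmetrically normalized self-looped adjacency
#'
#' Builds the binary symmetric adjacency `A` over the included interaction
#' pairs (event classes are ignored: an edge is an edge), adds self-loops
#' and normalizes: `A_hat = D^(-1/2) (A + I) D^(-1/2)` with `D` the degree
#' matrix of `A + I`. Drugs with no included edges still appear with a
#' self-loop only, so feature information can flow to isolated nodes.
#'
#' @param events a [DDIDataset-class] or a `data.frame` with columns
#'   `i`, `j` (a `class` column is ignored).
#' @param nDrugs number of drugs (rows/cols of the output); inferred from a
#'   `DDIDataset`.
#' @param edgeSubset optional `data.frame` of pairs (`i`, `j`) restricting
#'   the edges used, e.g. training-fold pairs only so held-out edges cannot
#'   leak through the graph channel.
#' @return symmetric sparse `Matrix` of shape `nDrugs x nDrugs` with all
#'   eigenvalues in `[-1, 1]` and a strictly positive diagonal.
#' @export
#' @examples
#' ev <- data.frame(i = 1, j = 2, class = 1)
#' buildAdjacency(ev, nDrugs = 2)  # every entry 1/2
buildAdjacency <- function(events, nDrugs = NULL, edgeSubset = NULL) {
  if (methods::is(events, "DDIDataset")) {
    if (is.null(nDrugs)) nDrugs <- nDrugs(events)
    events <- eventTable(events)
  }
  stopifnot(!is.null(nDrugs))
  pairs <- if (is.null(edgeSubset)) events else edgeSubset
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    if (!is.null(edgeSubset)) {
      key <- function(p) paste(pmin(p$i, p$j), pmax(p$i, p$j))
      if (!all(key(pairs) %in% key(as.data.frame(events))))
        stop("edgeSubset contains pairs absent from the event table")
    }
    pairs$class <- 1L
    pairs <- canonicalizePairs(pairs, nDrugs)
  }
  A <- Matrix::sparseMatrix(i = pairs$i, j = pairs$j, x = 1,
                            dims = c(nDrugs, nDrugs), symmetric = TRUE)
  Atilde <- A + Matrix::Diagonal(nDrugs)
  dinv <- 1 / sqrt(Matrix::rowSums(Atilde))
  Matrix::Diagonal(x = dinv) %*% Atilde %*% Matrix::Diagonal(x = dinv)
}
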
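#' Model configuration for the fusion network
#'
#' Assembles and validates the architecture hyperparameters of the two
#' channels. Both channels share the same per-layer widths (the delivery
#' operation mixes their activations elementwise at every layer, which
#' requires equal shapes). The last width must equal the number of event
#' classes C, since the fused embedding doubles as the class-score space.
#'
#' @param layerDims hidden widths, last entry = C. The 3-layer
#'   `c(2000, 256, 65)` stack is the default architecture for the
#'   572-drug / 65-class scale; smaller problems should scale it down.
#' @param alpha fusion coefficient in `[0, 1]` of the delivery operation
#'   (0 = topology channel only, 1 = feature channel only; 0.5 mixes
#'   equally).
#' @param reconWeight nonnegative weight lambda on the inner-product
#'   reconstruction loss.
#' @param attentionDim width of the attention projection (default: the
#'   final layer width).
#' @param sharedAttention logical; if `TRUE` (default) one projection
#'   `w`, bias `b` and attention vector `q` score both channels; if
#'   `FALSE`, `w` and `b` are channel-specific while `q` stays shared.
#' @param variant one of `"full"`, `"no_ae"`, `"no_gcn"`, `"no_att"`,
#'   `"no_delivery"` (ablations; see [runAblation()]).
#' @param seed integer seed for parameter initialization.
#' @return named list (class `"fusionConfig"`).
#' @export
fusionConfig <- function(layerDims = c(2000, 256, 65), alpha = 0.5,
                         reconWeight = 1.0, attentionDim = NULL,
                         sharedAttention = TRUE,
                         variant = c("full", "no_ae", "no_gcn", "no_att",
                                     "no_delivery"),
                         seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(layerDims) >= 1, alpha >= 0, alpha <= 1,
            reconWeight >= 0)
  if (is.null(attentionDim)) attentionDim <- layerDims[length(layerDims)]
  structure(list(layerDims = as.integer(layerDims), alpha = alpha,
                 reconWeight = reconWeight,
                 attentionDim = as.integer(attentionDim),
                 sharedAttention = isTRUE(sharedAttention),
                 variant = variant, seed = as.integer(seed)),
            class = "fusionConfig")
}

# Glorot-uniform matrix, U(-l, l) with l = sqrt(6 / (fanIn + fanOut)).
glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

#' Initialize all learnable parameters
#'
#' Glorot-uniform weights, zero biases, deterministic under the config
#' seed. The classifier head maps the pair-vector dimension (d, or 2d for
#' the concatenation combiner) to C.
#'
#' @param config a [fusionConfig()].
#' @param inputDim number of columns of the feature matrix X.
#' @param combiner pair combiner (decides the head input width).
#' @param head `"affine"` (default) or `"none"` (softmax the pair vector
#'   directly; only valid when the pair dimension equals C).
#' @return named list of parameter arrays.
#' @export
initFusionParams <- function(config, inputDim, combiner = "average",
                             head = c("affine", "none")) {
  head <- match.arg(head)
  set.seed(config$seed)
  dims <- c(inputDim, config$layerDims)
  L <- length(config$layerDims)
  C <- config$layerDims[L]
  p <- list()
  p$We <- lapply(seq_len(L), function(l) glorot(dims[l], dims[l + 1]))
  p$be <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  p$Wg <- lapply(seq_len(L), function(l) glorot(dims[l], dims[l + 1]))
  a <- config$attentionDim
  p$attW <- glorot(a, C)           # projection, applied to embedding rows
  p$attB <- numeric(a)
  p$attQ <- glorot(a, 1)[, 1]
  if (!config$sharedAttention) {
    p$attW2 <- glorot(a, C)
    p$attB2 <- numeric(a)
  }
  dp <- pairDim(combiner, C)
  if (head == "none" && dp != C)
    stop("head = 'none' requires the pair-vector dimension to equal C")
  if (head == "affine") {
    p$Wc <- glorot(dp, C)
    p$bc <- numeric(C)
  }
  attr(p, "head") <- head
  attr(p, "combiner") <- combiner
  p
}

#' One feature-channel (autoencoder encoder) layer
#'
#' `H_l = ReLU(H_{l-1} W_e + b_e)`; layer 0's input is X.
#'
#' @param Hprev input activation matrix.
#' @param W,b layer weight matrix and bias vector.
#' @param layer layer index, used only in error messages.
#' @return activation matrix.
#' @export
aeLayer <- function(Hprev, W, b, layer = NA) {
  if (ncol(Hprev) != nrow(W))
    stop(sprintf("feature-channel layer %s: input width %d != expected %d",
                 layer, ncol(Hprev), nrow(W)))
  pmax(sweep(Hprev %*% W, 2, b, `+`), 0)
}

#' Delivery operation: per-layer convex mix of the two channels
#'
#' `Z~ = (1 - alpha) * Z + alpha * H`, elementwise. This is how feature
#' information is injected into the topology channel at every layer,
#' counteracting oversmoothing.
#'
#' @param Z,H equal-shape activation matrices from the topology and
#'   feature channels.
#' @param alpha fusion coefficient in `[0, 1]`.
#' @return matrix of the same shape.
#' @export
delivery <- function(Z, H, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!all(dim(Z) == dim(H)))
    stop("delivery: Z and H must have identical shapes")
  (1 - alpha) * Z + alpha * H
}

#' One topology-channel (GCN) layer
#'
#' `Z_l = ReLU(A_hat %*% Z~_{l-1} %*% W)` over the normalized self-looped
#' adjacency.
#'
#' @param Ztilde delivery output of the previous layer (layer 1 receives X).
#' @param Ahat normalized adjacency from [buildAdjacency()].
#' @param W layer weight matrix.
#' @param layer layer index for error messages.
#' @return activation matrix.
#' @export
gcnLayer <- function(Ztilde, Ahat, W, layer = NA) {
  if (ncol(Ztilde) != nrow(W))
    stop(sprintf("topology-channel layer %s: input width %d != expected %d",
                 layer, ncol(Ztilde), nrow(W)))
  pmax(as.matrix(Ahat %*% Ztilde %*% W), 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inner-product reconstruction loss of the feature channel
#'
#' Mean squared error between `sigmoid(H %*% t(H))` and a drug-by-drug
#' similarity target (by default the mean per-view Jaccard matrix).
#'
#' @param H final feature-channel embedding (`n x d`).
#' @param target symmetric `n x n` similarity matrix.
#' @return nonnegative scalar.
#' @export
reconstructionLoss <- function(H, target) {
  if (nrow(H) != nrow(target) || nrow(target) != ncol(target))
    stop("reconstruction target must be n_drugs x n_drugs")
  R <- sigmoid(tcrossprod(H))
  mean((R - target)^2)
}

# Attention scores for one channel: s_i = q' tanh(w E_i' + b), vectorized
# over drugs. Returns list(scores, U) with U = tanh(E %*% t(w) + b) cached
# for backprop.
attScores <- function(E, w, b, q) {
  U <- tanh(sweep(E %*% t(w), 2, b, `+`))
  list(s = as.numeric(U %*% q), U = U)
}

#' Attention fusion of the two channel embeddings
#'
#' Per drug i, attention values `w_z_i = q' tanh(w Z_i' + b)` and
#' `w_h_i = q' tanh(w H_i' + b)` (same `w`, `b`, `q` when attention is
#' shared) are softmax-normalized into coefficients `(attZ_i, attH_i)`
#' summing to 1, and the fused embedding is
#' `E_i = attZ_i * Z_i + attH_i * H_i`.
#'
#' @param Z,H final-layer channel embeddings, equal shape.
#' @param params parameter list with `attW`, `attB`, `attQ` (and `attW2`,
#'   `attB2` for channel-specific projections).
#' @return a [FusedEmbedding-class].
#' @export
attentionFuse <- function(Z, H, params) {
  if (!all(dim(Z) == dim(H)))
    stop("attentionFuse: Z and H must have identical shapes")
  az <- attScores(Z, params$attW, params$attB, params$attQ)
  wh <- if (is.null(params$attW2)) params$attW else params$attW2
  bh <- if (is.null(params$attB2)) params$attB else params$attB2
  ah <- attScores(H, wh, bh, params$attQ)
  if (!all(is.finite(az$s)) || !all(is.finite(ah$s)))
    stop("non-finite attention activations (scores for Z/H channels)")
  m <- pmax(az$s, ah$s)
  ez <- exp(az$s - m); eh <- exp(ah$s - m)
  attZ <- ez / (ez + eh); attH <- eh / (ez + eh)
  E <- Z * attZ + H * attH
  new("FusedEmbedding", E = E, Z = unname(Z), H = unname(H),
      attZ = attZ, attH = attH)
}

#' Full forward pass of the fusion network
#'
#' Runs the feature channel and the topology channel in lockstep for L
#' layers: at layer l the delivery operation mixes `Z_{l-1}` with
#' `H_{l-1}` before graph propagation (layer 1 receives X on both inputs,
#' so its delivery is a no-op), then fuses the two final embeddings with
#' attention. Ablation variants alter the wiring:
#' `no_ae` drops the feature channel (pure GCN, E = Z);
#' `no_gcn` drops the topology channel (E = H);
#' `no_att` sums the two final embeddings;
#' `no_delivery` sets alpha = 0 but keeps attention.
#'
#' @param X feature matrix (a [DrugFeatureTable-class] or plain matrix).
#' @param Ahat normalized adjacency.
#' @param params parameter list from [initFusionParams()].
#' @param config a [fusionConfig()].
#' @param keepCache return intermediate activations (for training).
#' @return a [FusedEmbedding-class]; with `keepCache = TRUE`, a list
#'   `list(emb, cache)`.
#' @export
fuseForward <- function(X, Ahat, params, config, keepCache = FALSE) {
  if (methods::is(X, "DrugFeatureTable")) X <- X@X
  X <- unname(as.matrix(X))
  L <- length(config$layerDims)
  variant <- config$variant
  alpha <- if (variant %in% c("no_ae", "no_delivery")) 0 else config$alpha
  useAE <- variant != "no_ae"
  useGCN <- variant != "no_gcn"
  H <- vector("list", L + 1); Z <- vector("list", L + 1)
  preH <- vector("list", L); preZ <- vector("list", L)
  Zt <- vector("list", L)
  H[[1]] <- X; Z[[1]] <- X
  for (l in seq_len(L)) {
    if (useAE) {
      preH[[l]] <- sweep(H[[l]] %*% params$We[[l]], 2, params$be[[l]], `+`)
      H[[l + 1]] <- pmax(preH[[l]], 0)
    }
    if (useGCN) {
      Zt[[l]] <- if (useAE) delivery(Z[[l]], H[[l]], alpha) else Z[[l]]
      preZ[[l]] <- as.matrix(Ahat %*% Zt[[l]] %*% params$Wg[[l]])
      Z[[l + 1]] <- pmax(preZ[[l]], 0)
    }
  }
  emb <- switch(variant,
    no_ae = new("FusedEmbedding", E = Z[[L + 1]], Z = Z[[L + 1]],
                H = matrix(0, nrow(X), config$layerDims[L]),
                attZ = rep(1, nrow(X)), attH = rep(0, nrow(X))),
    no_gcn = new("FusedEmbedding", E = H[[L + 1]],
                 Z = matrix(0, nrow(X), config$layerDims[L]),
                 H = H[[L + 1]],
                 attZ = rep(0, nrow(X)), attH = rep(1, nrow(X))),
    no_att = new("FusedEmbedding", E = Z[[L + 1]] + H[[L + 1]],
                 Z = Z[[L + 1]], H = H[[L + 1]],
                 attZ = rep(NA_real_, nrow(X)), attH = rep(NA_real_, nrow(X))),
    attentionFuse(Z[[L + 1]], H[[L + 1]], params))
  if (!keepCache) return(emb)
  list(emb = emb,
       cache = list(H = H, Z = Z, preH = preH, preZ = preZ, Zt = Zt,
                    alpha = alpha, useAE = useAE, useGCN = useGCN))
}
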
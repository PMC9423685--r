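test_that("aeLayer applies the affine map with ReLU", {
  X <- matrix(c(1, 2, -1, 0.5, 3, -2), 2, 3)
  I3 <- diag(3)
  expect_equal(aeLayer(pmax(X, 0), I3, numeric(3)), pmax(X, 0))  # identity
  expect_equal(aeLayer(matrix(-1, 2, 3), I3, numeric(3)),
               matrix(0, 2, 3))                                  # full clamp
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4); W <- matrix(rnorm(8), 4, 2); b <- rnorm(2)
  expect_equal(aeLayer(A, W, b),
               pmax(A %*% W + matrix(b, 3, 2, byrow = TRUE), 0))
  expect_error(aeLayer(A, matrix(0, 3, 2), numeric(2), layer = 2), "layer 2")
})

test_that("delivery is the convex channel mix with exact endpoints", {
  set.seed(2)
  Z <- matrix(rnorm(12), 3, 4); H <- matrix(rnorm(12), 3, 4)
  expect_identical(delivery(Z, H, 0), Z)
  expect_identical(delivery(Z, H, 1), H)
  expect_equal(delivery(matrix(2, 2, 2), matrix(0, 2, 2), 0.5),
               matrix(1, 2, 2))
  # linearity: delivery(Z,H,a) + delivery(H,Z,a) == Z + H (to rounding)
  expect_equal(delivery(Z, H, 0.3) + delivery(H, Z, 0.3), Z + H,
               tolerance = 1e-15)
  expect_error(delivery(Z, H[1:2, ], 0.5), "identical shapes")
})

test_that("gcnLayer propagates over the normalized adjacency", {
  # isolated node: A_hat = [[1]], identity weights pass features through
  expect_equal(gcnLayer(matrix(c(1, 2), 1, 2), matrix(1, 1, 1), diag(2)),
               matrix(c(1, 2), 1, 2))
  # 2-node single-edge graph: A_hat all 0.5 averages the rows
  A2 <- buildAdjacency(data.frame(i = 1, j = 2, class = 1), nDrugs = 2)
  expect_equal(gcnLayer(diag(2) * 2, A2, diag(2)), matrix(1, 2, 2))
  expect_equal(gcnLayer(diag(2), A2, matrix(0, 2, 2)), matrix(0, 2, 2))
})

test_that("attention coefficients are a proper two-way softmax", {
  set.seed(3)
  cfg <- fusionConfig(layerDims = c(5, 4), seed = 3)
  p <- initFusionParams(cfg, 6)
  Z <- matrix(rnorm(24), 6, 4)
  # identical channels force 0.5/0.5 and E = Z
  fe <- attentionFuse(Z, Z, p)
  expect_equal(fe@attZ, rep(0.5, 6))
  expect_equal(fe@E, unname(Z))
  # q = 0 gives equal scores regardless of the channels
  p0 <- p; p0$attQ[] <- 0
  H <- matrix(rnorm(24), 6, 4)
  expect_equal(attentionFuse(Z, H, p0)@attZ, rep(0.5, 6))
  # contract on random inputs
  for (s in 1:5) {
    set.seed(s)
    Z <- matrix(rnorm(20, sd = 2), 5, 4); H <- matrix(rnorm(20, sd = 2), 5, 4)
    fe <- attentionFuse(Z, H, p)
    expect_equal(fe@attZ + fe@attH, rep(1, 5), tolerance = 1e-6)
    expect_true(all(fe@attZ > 0 & fe@attZ < 1))
  }
})

test_that("attention fusion agrees with the per-drug scalar oracle", {
  set.seed(9)
  cfg <- fusionConfig(layerDims = c(8, 6), seed = 9)
  p <- initFusionParams(cfg, 10)
  Z <- matrix(rnorm(30), 5, 6); H <- matrix(rnorm(30), 5, 6)
  fe <- attentionFuse(Z, H, p)
  orc <- oracleAttention(Z, H, p)
  expect_equal(fe@E, orc$E, tolerance = 1e-10)
  expect_equal(fe@attZ, orc$attZ, tolerance = 1e-10)
  expect_equal(fe@attH, orc$attH, tolerance = 1e-10)
})

test_that("reconstruction loss is the MSE of the sigmoid inner product", {
  set.seed(4)
  H <- matrix(rnorm(12), 4, 3)
  exact <- 1 / (1 + exp(-tcrossprod(H)))
  expect_equal(reconstructionLoss(H, exact), 0)
  expect_equal(reconstructionLoss(matrix(0, 3, 2), matrix(0.5, 3, 3)), 0)
  target <- matrix(runif(16), 4, 4)
  manual <- 0
  S <- 1 / (1 + exp(-H %*% t(H)))
  for (a in 1:4) for (b in 1:4) manual <- manual + (S[a, b] - target[a, b])^2
  expect_equal(reconstructionLoss(H, target), manual / 16)
  expect_error(reconstructionLoss(H, matrix(0, 2, 2)), "n_drugs")
})

test_that("the no_ae forward pass is bit-identical to an independent GCN", {
  set.seed(5)
  n <- 10; d0 <- 12
  X <- matrix(runif(n * d0), n, d0)
  ev <- toyEvents(n, 15, 2, seed = 5)
  Ahat <- buildAdjacency(ev, nDrugs = n)
  cfg <- fusionConfig(layerDims = c(7, 4), variant = "no_ae", seed = 5)
  p <- initFusionParams(cfg, d0)
  emb <- fuseForward(X, Ahat, p, cfg)
  expect_identical(emb@E, oracleGCNForward(X, Ahat, p$Wg))
  expect_identical(emb@attZ, rep(1, n))
})

test_that("forward pass keeps per-drug attention normalized and variants wire correctly", {
  set.seed(6)
  n <- 8; d0 <- 9
  X <- matrix(runif(n * d0), n, d0)
  Ahat <- buildAdjacency(toyEvents(n, 10, 2, seed = 6), nDrugs = n)
  for (variant in c("full", "no_delivery")) {
    cfg <- fusionConfig(layerDims = c(6, 3), variant = variant, seed = 6)
    p <- initFusionParams(cfg, d0)
    emb <- fuseForward(X, Ahat, p, cfg)
    expect_equal(emb@attZ + emb@attH, rep(1, n), tolerance = 1e-6)
  }
  cfg <- fusionConfig(layerDims = c(6, 3), variant = "no_att", seed = 6)
  p <- initFusionParams(cfg, d0)
  emb <- fuseForward(X, Ahat, p, cfg)
  expect_equal(emb@E, emb@Z + emb@H)
  cfg <- fusionConfig(layerDims = c(6, 3), variant = "no_gcn", seed = 6)
  emb <- fuseForward(X, Ahat, initFusionParams(cfg, d0), cfg)
  expect_equal(emb@E, emb@H)
})

test_that("permuting the drugs permutes the embedding identically", {
  set.seed(7)
  n <- 9
  ds <- simulateDDIData(syntheticConfig(nDrugs = n, viewDims = c(10, 6),
                                        nCommunities = 3, nClasses = 3,
                                        seed = 7))
  ft <- suppressWarnings(buildFeatureTable(ds))
  Ahat <- as.matrix(buildAdjacency(ds))
  cfg <- fusionConfig(layerDims = c(5, 3), seed = 7)
  p <- initFusionParams(cfg, ncol(ft@X))
  emb <- fuseForward(ft@X, Ahat, p, cfg)

  perm <- sample(n)
  # X columns are drug-indexed per view: permute rows and within-view cols
  nv <- length(ft@viewOffsets)
  colPerm <- unlist(lapply(seq_len(nv), function(v) (v - 1L) * n + perm))
  Xp <- ft@X[perm, colPerm]
  Ap <- Ahat[perm, perm]
  pp <- p
  pp$We[[1]] <- p$We[[1]][colPerm, , drop = FALSE]
  pp$Wg[[1]] <- p$Wg[[1]][colPerm, , drop = FALSE]
  embP <- fuseForward(Xp, Ap, pp, cfg)
  expect_equal(embP@E, emb@E[perm, ], tolerance = 1e-12)
  expect_equal(embP@attZ, emb@attZ[perm], tolerance = 1e-12)
})

test_that("delivery counteracts embedding collapse in deep stacks", {
  # 2-block graph, 8 propagation layers: with alpha = 0.5 the feature
  # channel keeps re-injecting node-specific signal, so node embeddings
  # stay more spread out than the pure-GCN (alpha = 0) run
  set.seed(8)
  n <- 20
  comm <- rep(1:2, each = n / 2)
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- comm[prs[, 1]] == comm[prs[, 2]]
  keep <- runif(nrow(prs)) < ifelse(same, 0.6, 0.05)
  ev <- data.frame(i = prs[keep, 1], j = prs[keep, 2], class = 1)
  Ahat <- buildAdjacency(ev, nDrugs = n)
  X <- matrix(runif(n * 16), n, 16)
  dims <- rep(16, 8)
  spread <- sapply(c(0.5, 0), function(a) {
    cfg <- fusionConfig(layerDims = dims, alpha = a, seed = 8)
    p <- initFusionParams(cfg, 16)
    emb <- fuseForward(X, Ahat, p, cfg)
    mean(dist(emb@Z))
  })
  expect_gt(spread[1], spread[2])
})

test_that("model configuration is validated", {
  expect_error(fusionConfig(layerDims = integer()), "layerDims")
  expect_error(fusionConfig(alpha = 1.5), "alpha")
  cfg <- fusionConfig(layerDims = c(10, 4))
  expect_equal(cfg$attentionDim, 4L)   # defaults to the final width
})
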
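#' DGCNN configuration
#'
#' Hyperparameters of the EdgeConv segmentation network. The `"paper"` profile
#' is the published training configuration (8192 input points, learning rate
#' 0.001, 200 epochs, batch size 20, Adam); the `"desk"` profile is a reduced
#' configuration (1024 points, 30 epochs, batch 4, narrower global descriptor)
#' sized for CPU-only validation runs.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param k_neighbors kNN graph size for EdgeConv.
#' @param edgeconv_widths List of per-block MLP width vectors.
#' @param emb_width Width of the global descriptor.
#' @param head_widths Widths of the per-point segmentation head.
#' @param n_points Input cloud size (clouds are downsampled to this on load).
#' @param learning_rate,epochs,batch_size Adam optimisation settings.
#' @param n_classes Number of semantic classes (2: stem, silique).
#' @param use_tnet Apply the learned 3 x 3 input alignment transform.
#' @param seed Integer seed for initialization and batching.
#' @return A `dgcnn_config` list.
#' @export
dgcnn_config <- function(profile = c("paper", "desk"), k_neighbors = 20,
                         edgeconv_widths = list(c(64, 64), c(64, 64), 64),
                         emb_width = NULL, head_widths = c(256, 128),
                         n_points = NULL, learning_rate = 0.001,
                         epochs = NULL, batch_size = NULL, n_classes = 2,
                         use_tnet = TRUE, seed = 0) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    n_points <- n_points %||% 8192
    epochs <- epochs %||% 200
    batch_size <- batch_size %||% 20
    emb_width <- emb_width %||% 1024
  } else {
    n_points <- n_points %||% 1024
    epochs <- epochs %||% 30
    batch_size <- batch_size %||% 4
    emb_width <- emb_width %||% 256
  }
  stopifnot(k_neighbors >= 1, k_neighbors < n_points,
            all(unlist(edgeconv_widths) > 0), emb_width > 0,
            all(head_widths > 0), learning_rate >= 0, epochs >= 1,
            batch_size >= 1, n_classes >= 2)
  structure(list(profile = profile, k_neighbors = as.integer(k_neighbors),
                 edgeconv_widths = lapply(edgeconv_widths, as.integer),
                 emb_width = as.integer(emb_width),
                 head_widths = as.integer(head_widths),
                 n_points = as.integer(n_points),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_classes = as.integer(n_classes), use_tnet = use_tnet,
                 seed = as.integer(seed)),
            class = "dgcnn_config")
}

#' Build a k-nearest-neighbour graph
#'
#' Row `i` of the result lists the `k` nearest points to point `i` by
#' Euclidean distance (self excluded, distance ties broken toward the lower
#' index), nearest first.
#'
#' @param coords N x 3 coordinate matrix (or point cloud).
#' @param k Number of neighbours, `k < N`.
#' @return An N x k integer matrix of 1-based neighbour indices.
#' @export
build_knn_graph <- function(coords, k) {
  if (is.data.frame(coords)) coords <- cloud_coords(as_point_cloud(coords))
  coords <- as.matrix(coords)
  if (k >= nrow(coords)) abort("k must be smaller than the number of points")
  cpp_knn_graph(coords, as.integer(k))
}

# brute-force knn in feature space (any dimension); ties toward lower index
knn_feature_graph <- function(f, k) {
  n <- nrow(f)
  rs <- rowSums(f * f)
  d2 <- outer(rs, rep(1, n)) + outer(rep(1, n), rs) - 2 * tcrossprod(f)
  diag(d2) <- Inf
  g <- matrix(0L, n, k)
  for (i in seq_len(n)) g[i, ] <- order(d2[i, ])[seq_len(k)]
  g
}

edge_tensor <- function(f, graph) {
  n <- nrow(f)
  k <- ncol(graph)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(graph))
  cbind(f[ii, , drop = FALSE], f[jj, , drop = FALSE] - f[ii, , drop = FALSE])
}

edge_tensor_backward <- function(dE, graph, fdim) {
  n <- nrow(graph)
  k <- ncol(graph)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(graph))
  d1 <- dE[, seq_len(fdim), drop = FALSE]
  d2 <- dE[, fdim + seq_len(fdim), drop = FALSE]
  df <- rowsum(d1 - d2, ii) # every i appears k times, so rows are 1..n
  add <- rowsum(d2, jj)
  tgt <- as.integer(rownames(add))
  df[tgt, ] <- df[tgt, , drop = FALSE] + add
  df
}

pool_max_k <- function(E, n, k) {
  sel <- seq(1L, n * k, by = k)
  mx <- E[sel, , drop = FALSE]
  am <- matrix(1L, n, ncol(E))
  if (k > 1) for (r in 2:k) {
    Er <- E[sel + (r - 1L), , drop = FALSE]
    upd <- Er > mx
    if (any(upd)) {
      mx[upd] <- Er[upd]
      am[upd] <- r
    }
  }
  list(out = mx, argmax = am)
}

unpool_max_k <- function(dout, am, n, k) {
  cdim <- ncol(dout)
  dE <- matrix(0, n * k, cdim)
  li <- ((seq_len(n) - 1L) * k + as.vector(am)) +
    rep((seq_len(cdim) - 1L) * (n * k), each = n)
  dE[li] <- as.vector(dout)
  dE
}

pool_max_g <- function(X) {
  am <- max.col(t(X), ties.method = "first")
  list(out = X[cbind(am, seq_len(ncol(X)))], argmax = am)
}

unpool_max_g <- function(dout, am, n) {
  dX <- matrix(0, n, length(dout))
  dX[cbind(am, seq_along(dout))] <- dout
  dX
}

glorot_mat <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -s, s), fin, fout)
}

#' Initialise an untrained DGCNN model
#'
#' Weights are Glorot-initialised from the config seed; the alignment
#' transform's final layer is zero-initialised with an identity bias, so the
#' untrained transform is exactly the identity.
#'
#' @param config A [dgcnn_config()].
#' @return A `dgcnn_model` with untrained parameters.
#' @export
dgcnn_init <- function(config = dgcnn_config()) {
  withr::with_seed(config$seed, {
    p <- list()
    if (config$use_tnet) {
      p$tnet_mlp_W <- glorot_mat(6, 64)
      p$tnet_mlp_b <- rep(0, 64)
      p$tnet_fc1_W <- glorot_mat(64, 32)
      p$tnet_fc1_b <- rep(0, 32)
      p$tnet_fc2_W <- matrix(0, 32, 9)
      p$tnet_fc2_b <- as.vector(diag(3))
    }
    fin <- 3L
    for (b in seq_along(config$edgeconv_widths)) {
      din <- 2L * fin
      for (l in seq_along(config$edgeconv_widths[[b]])) {
        w <- config$edgeconv_widths[[b]][l]
        p[[sprintf("conv%d_%d_W", b, l)]] <- glorot_mat(din, w)
        p[[sprintf("conv%d_%d_b", b, l)]] <- rep(0, w)
        din <- w
      }
      fin <- tail(config$edgeconv_widths[[b]], 1)
    }
    locals_dim <- sum(vapply(config$edgeconv_widths, function(w) tail(w, 1), 1L))
    p$emb_W <- glorot_mat(locals_dim, config$emb_width)
    p$emb_b <- rep(0, config$emb_width)
    din <- locals_dim + config$emb_width
    for (l in seq_along(config$head_widths)) {
      p[[sprintf("head%d_W", l)]] <- glorot_mat(din, config$head_widths[l])
      p[[sprintf("head%d_b", l)]] <- rep(0, config$head_widths[l])
      din <- config$head_widths[l]
    }
    p$out_W <- glorot_mat(din, config$n_classes)
    p$out_b <- rep(0, config$n_classes)
    structure(list(params = p, config = config, log = NULL),
              class = "dgcnn_model")
  })
}

lin_fwd <- function(X, W, b) sweep(X %*% W, 2, b, "+")

# Full forward pass; returns scores and (optionally) every intermediate
# needed by dgcnn_backward.
dgcnn_forward <- function(params, coords, config, keep_cache = FALSE) {
  n <- nrow(coords)
  k <- min(config$k_neighbors, n - 1L)
  cache <- list(coords = coords, k = k)
  if (config$use_tnet) {
    g0 <- build_knn_graph(coords, k)
    E0 <- edge_tensor(coords, g0)
    Z0 <- lin_fwd(E0, params$tnet_mlp_W, params$tnet_mlp_b)
    A0 <- pmax(Z0, 0)
    pk <- pool_max_k(A0, n, k)
    pg <- pool_max_g(pk$out)
    Z1 <- as.vector(pg$out %*% params$tnet_fc1_W) + params$tnet_fc1_b
    A1 <- pmax(Z1, 0)
    v <- as.vector(A1 %*% params$tnet_fc2_W) + params$tnet_fc2_b
    Tm <- matrix(v, 3, 3)
    xt <- coords %*% Tm
    cache$tnet <- list(g0 = g0, E0 = E0, Z0 = Z0, A0 = A0, pk = pk, pg = pg,
                       Z1 = Z1, A1 = A1, Tm = Tm)
  } else {
    xt <- coords
  }
  cache$xt <- xt
  f <- xt
  locals <- list()
  blocks <- list()
  for (b in seq_along(config$edgeconv_widths)) {
    graph <- if (ncol(f) == 3) build_knn_graph(f, k) else knn_feature_graph(f, k)
    E <- edge_tensor(f, graph)
    layers <- list()
    X <- E
    for (l in seq_along(config$edgeconv_widths[[b]])) {
      Z <- lin_fwd(X, params[[sprintf("conv%d_%d_W", b, l)]],
                   params[[sprintf("conv%d_%d_b", b, l)]])
      A <- pmax(Z, 0)
      layers[[l]] <- list(X = X, Z = Z)
      X <- A
    }
    pk <- pool_max_k(X, n, k)
    f_out <- pk$out
    blocks[[b]] <- list(graph = graph, fdim = ncol(f), layers = layers, pk = pk)
    locals[[b]] <- f_out
    f <- f_out
  }
  L <- do.call(cbind, locals)
  Ze <- lin_fwd(L, params$emb_W, params$emb_b)
  Ae <- pmax(Ze, 0)
  pg <- pool_max_g(Ae)
  G <- matrix(pg$out, n, length(pg$out), byrow = TRUE)
  X <- cbind(L, G)
  head_layers <- list()
  for (l in seq_along(config$head_widths)) {
    Z <- lin_fwd(X, params[[sprintf("head%d_W", l)]],
                 params[[sprintf("head%d_b", l)]])
    A <- pmax(Z, 0)
    head_layers[[l]] <- list(X = X, Z = Z)
    X <- A
  }
  scores <- lin_fwd(X, params$out_W, params$out_b)
  if (keep_cache) {
    cache$blocks <- blocks
    cache$L <- L
    cache$emb <- list(Ze = Ze, Ae = Ae, pg = pg)
    cache$head <- head_layers
    cache$head_out_X <- X
    list(scores = scores, cache = cache)
  } else {
    list(scores = scores)
  }
}

dgcnn_backward <- function(params, cache, config, dscores) {
  n <- nrow(cache$coords)
  k <- cache$k
  g <- list()
  g$out_W <- crossprod(cache$head_out_X, dscores)
  g$out_b <- colSums(dscores)
  dX <- dscores %*% t(params$out_W)
  for (l in rev(seq_along(config$head_widths))) {
    lay <- cache$head[[l]]
    dZ <- dX * (lay$Z > 0)
    g[[sprintf("head%d_W", l)]] <- crossprod(lay$X, dZ)
    g[[sprintf("head%d_b", l)]] <- colSums(dZ)
    dX <- dZ %*% t(params[[sprintf("head%d_W", l)]])
  }
  locals_dim <- ncol(cache$L)
  dL <- dX[, seq_len(locals_dim), drop = FALSE]
  dG <- dX[, locals_dim + seq_len(ncol(dX) - locals_dim), drop = FALSE]
  dg_vec <- colSums(dG)
  dAe <- unpool_max_g(dg_vec, cache$emb$pg$argmax, n)
  dZe <- dAe * (cache$emb$Ze > 0)
  g$emb_W <- crossprod(cache$L, dZe)
  g$emb_b <- colSums(dZe)
  dL <- dL + dZe %*% t(params$emb_W)
  # split dL across blocks, then walk blocks in reverse; each block's input
  # gradient feeds the previous block's output (dynamic-graph indices fixed)
  widths_out <- vapply(config$edgeconv_widths, function(w) tail(w, 1), 1L)
  offs <- cumsum(c(0, widths_out))
  dlocals <- lapply(seq_along(widths_out), function(b)
    dL[, offs[b] + seq_len(widths_out[b]), drop = FALSE])
  dxt <- NULL
  for (b in rev(seq_along(config$edgeconv_widths))) {
    blk <- cache$blocks[[b]]
    dout <- dlocals[[b]]
    if (!is.null(dxt)) dout <- dout + dxt # gradient from the next block's input
    dX <- unpool_max_k(dout, blk$pk$argmax, n, k)
    for (l in rev(seq_along(config$edgeconv_widths[[b]]))) {
      lay <- blk$layers[[l]]
      dZ <- dX * (lay$Z > 0)
      g[[sprintf("conv%d_%d_W", b, l)]] <- crossprod(lay$X, dZ)
      g[[sprintf("conv%d_%d_b", b, l)]] <- colSums(dZ)
      dX <- dZ %*% t(params[[sprintf("conv%d_%d_W", b, l)]])
    }
    dxt <- edge_tensor_backward(dX, blk$graph, blk$fdim)
  }
  if (config$use_tnet) {
    tc <- cache$tnet
    dT <- crossprod(cache$coords, dxt)
    dv <- as.vector(dT)
    g$tnet_fc2_W <- outer(tc$A1, dv)
    g$tnet_fc2_b <- dv
    dA1 <- as.vector(params$tnet_fc2_W %*% dv)
    dZ1 <- dA1 * (tc$Z1 > 0)
    g$tnet_fc1_W <- outer(as.vector(tc$pg$out), dZ1)
    g$tnet_fc1_b <- dZ1
    dpg <- as.vector(params$tnet_fc1_W %*% dZ1)
    dPk <- unpool_max_g(dpg, tc$pg$argmax, n)
    dA0 <- unpool_max_k(dPk, tc$pk$argmax, n, k)
    dZ0 <- dA0 * (tc$Z0 > 0)
    g$tnet_mlp_W <- crossprod(tc$E0, dZ0)
    g$tnet_mlp_b <- colSums(dZ0)
  }
  g
}

#' Shared EdgeConv feature computation
#'
#' For each point `i` and neighbour `j` in the graph, the edge input
#' concatenates the point's feature with the neighbour difference
#' `(f_j - f_i)`; a shared MLP (linear + ReLU per width) maps each edge and
#' max-pooling over the `k` neighbours yields the point's output feature.
#'
#' @param features N x f input feature matrix.
#' @param graph N x k neighbour-index matrix (see [build_knn_graph()]).
#' @param mlp An [edgeconv_mlp()] weight list.
#' @return An N x a_n output feature matrix (a_n = last MLP width).
#' @export
edgeconv_features <- function(features, graph, mlp) {
  features <- as.matrix(features)
  if (nrow(graph) != nrow(features)) {
    abort("graph and feature matrix disagree on the number of points")
  }
  if (ncol(mlp[[1]]$W) > 0 && nrow(mlp[[1]]$W) != 2 * ncol(features)) {
    abort("MLP input width must equal twice the feature width")
  }
  X <- edge_tensor(features, graph)
  for (l in seq_along(mlp)) X <- pmax(lin_fwd(X, mlp[[l]]$W, mlp[[l]]$b), 0)
  pool_max_k(X, nrow(features), ncol(graph))$out
}

#' Create shared-MLP weights for [edgeconv_features()]
#'
#' @param in_dim Input feature width f (edge inputs have width `2 * f`).
#' @param widths MLP layer widths.
#' @param seed Integer seed.
#' @return A list of `list(W, b)` layers.
#' @export
edgeconv_mlp <- function(in_dim, widths, seed = 0) {
  withr::with_seed(seed, {
    din <- 2L * in_dim
    lapply(widths, function(w) {
      W <- glorot_mat(din, w)
      din <<- w
      list(W = W, b = rep(0, w))
    })
  })
}

#' Input alignment transform
#'
#' Returns the model's estimated 3 x 3 alignment matrix for a cloud: edge
#' features on the coordinate kNN graph, max-pooled locally and globally, then
#' two fully connected layers whose final layer is zero-initialised with an
#' identity bias -- an untrained model therefore returns the identity.
#'
#' @param coords N x 3 coordinates (or point cloud).
#' @param model A `dgcnn_model` (e.g. from [dgcnn_init()]).
#' @return A 3 x 3 matrix.
#' @export
spatial_transform <- function(coords, model) {
  if (is.data.frame(coords)) coords <- cloud_coords(as_point_cloud(coords))
  coords <- as.matrix(coords)
  config <- model$config
  if (!config$use_tnet) return(diag(3))
  fw <- dgcnn_forward(model$params, coords, config, keep_cache = TRUE)
  fw$cache$tnet$Tm
}

#' Mean cross-entropy segmentation loss
#'
#' The per-point loss is `-log(exp(x[label]) / sum_j exp(x[j]))` on the raw
#' class scores; the reported value is its mean over points. Invariant under
#' adding a constant to all of a point's scores.
#'
#' @param scores N x c raw class-score matrix.
#' @param labels Length-N integer labels in `0:(c-1)`.
#' @return Non-negative mean loss.
#' @export
segmentation_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  if (length(labels) != nrow(scores)) abort("labels must match score rows")
  if (any(labels < 0) || any(labels >= ncol(scores))) {
    abort("labels out of range for the score columns")
  }
  m <- do.call(pmax, as.data.frame(scores))
  lse <- m + log(rowSums(exp(scores - m)))
  mean(lse - scores[cbind(seq_along(labels), labels + 1L)])
}

softmax_grad <- function(scores, labels) {
  m <- do.call(pmax, as.data.frame(scores))
  e <- exp(scores - m)
  p <- e / rowSums(e)
  p[cbind(seq_along(labels), labels + 1L)] <-
    p[cbind(seq_along(labels), labels + 1L)] - 1
  p / nrow(scores)
}

normalize_cloud_coords <- function(coords) {
  ctr <- colMeans(coords)
  rel <- sweep(coords, 2, ctr)
  s <- max(sqrt(rowSums(rel^2)))
  if (s == 0) s <- 1
  rel / s
}

prepare_training_cloud <- function(cloud, n_points, seed_offset = 0) {
  cloud <- as_point_cloud(cloud)
  if (!is_labeled(cloud)) abort("training clouds must be labeled")
  if (nrow(cloud) < n_points) {
    abort("training clouds must have at least n_points points")
  }
  if (nrow(cloud) > n_points) {
    cloud <- downsample(cloud, n_points, method = "fps", start = 1L)
  }
  list(coords = normalize_cloud_coords(cloud_coords(cloud)),
       labels = cloud$label)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Train the DGCNN segmenter
#'
#' Clouds are farthest-point downsampled to `config$n_points`, centred and
#' scaled to the unit sphere, and optimised with Adam on the mean
#' cross-entropy loss in batches of `config$batch_size` for `config$epochs`
#' epochs. Deterministic for a fixed config seed.
#'
#' @param train_set,val_set Lists of labeled point clouds (validation may be
#'   empty).
#' @param config A [dgcnn_config()].
#' @param checkpoint Optional path; the trained model is saved there with
#'   [saveRDS()].
#' @param verbose Print per-epoch progress.
#' @return A trained `dgcnn_model`; `model$log` holds the per-epoch tibble
#'   (`epoch`, `train_loss`, `val_loss`, `val_acc`).
#' @export
dgcnn_train <- function(train_set, val_set = list(), config = dgcnn_config(),
                        checkpoint = NULL, verbose = FALSE) {
  if (length(train_set) == 0) abort("empty training set")
  model <- dgcnn_init(config)
  params <- model$params
  tr <- lapply(train_set, prepare_training_cloud, n_points = config$n_points)
  va <- lapply(val_set, prepare_training_cloud, n_points = config$n_points)
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  log_rows <- vector("list", config$epochs)
  step <- 0L
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(tr))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bt in batches) {
        grads <- NULL
        b_loss <- 0
        for (ci in bt) {
          fw <- dgcnn_forward(params, tr[[ci]]$coords, config,
                              keep_cache = TRUE)
          b_loss <- b_loss + segmentation_loss(fw$scores, tr[[ci]]$labels)
          ds <- softmax_grad(fw$scores, tr[[ci]]$labels)
          gi <- dgcnn_backward(params, fw$cache, config, ds)
          grads <- if (is.null(grads)) gi else
            Map(function(a, b) a + b, grads, gi[names(grads)])
        }
        grads <- lapply(grads, function(gr) gr / length(bt))
        step <- step + 1L
        upd <- adam_step(params, grads, state, config$learning_rate, step)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + b_loss
      }
      ep_loss <- ep_loss / length(tr)
      vl <- va_acc <- NA_real_
      if (length(va) > 0) {
        vl <- 0
        correct <- 0L
        total <- 0L
        for (vc in va) {
          fw <- dgcnn_forward(params, vc$coords, config)
          vl <- vl + segmentation_loss(fw$scores, vc$labels)
          pred <- max.col(fw$scores, ties.method = "first") - 1L
          correct <- correct + sum(pred == vc$labels)
          total <- total + length(vc$labels)
        }
        vl <- vl / length(va)
        va_acc <- correct / total
      }
      log_rows[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss,
                                  val_loss = vl, val_acc = va_acc)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.4f",
                        epoch, ep_loss, vl, va_acc))
      }
    }
  })
  model$params <- params
  model$log <- dplyr::bind_rows(log_rows)
  if (!is.null(checkpoint)) saveRDS(model, checkpoint)
  model
}

#' Segment a cloud with a trained model
#'
#' Pure forward pass (no test-time adaptation): the cloud is centred and
#' scaled to the unit sphere, per-point raw class scores are computed, and the
#' predicted label is the score argmax. Clouds of any size `> k_neighbors` are
#' accepted; smaller clouds are padded by resampling with replacement.
#'
#' @param cloud A point cloud.
#' @param model A trained `dgcnn_model`.
#' @return The cloud with a predicted `label` column plus raw score columns
#'   `score_stem` and `score_silique` (pre-softmax, as fed to the loss).
#' @export
segment_cloud <- function(cloud, model) {
  cloud <- as_point_cloud(cloud)
  config <- model$config
  n <- nrow(cloud)
  idx <- seq_len(n)
  if (n <= config$k_neighbors) {
    idx <- rep_len(seq_len(n), config$k_neighbors + 1L)
  }
  coords <- normalize_cloud_coords(cloud_coords(cloud)[idx, , drop = FALSE])
  fw <- dgcnn_forward(model$params, coords, config)
  scores <- fw$scores[seq_len(n), , drop = FALSE]
  out <- cloud
  out$label <- as.integer(max.col(scores, ties.method = "first") - 1L)
  out$score_stem <- scores[, 1]
  out$score_silique <- scores[, 2]
  as_point_cloud(out)
}

#' Geometric baseline stem/silique classifier
#'
#' A non-learned stand-in for the trained network so the mapping and counting
#' stages can be exercised without training: a point is labeled silique when
#' its local neighbourhood is strongly linear (PCA linearity
#' `(l1 - l2) / l1` over the points within `radius`, at least
#' `linearity_threshold`) and its height exceeds the `height_quantile` of the
#' cloud's z values (`height_quantile = 0` disables the height gate; `1`
#' labels everything stem). The neighbourhood radius should be comparable to
#' the pod length scale so a pod's axial extent dominates its radial noise.
#'
#' @param cloud A point cloud of at least 10 points.
#' @param height_quantile Height gate quantile in `[0, 1]`.
#' @param radius Neighbourhood radius (m).
#' @param linearity_threshold Minimum PCA linearity for a silique call.
#' @return The cloud with a predicted `label` column and a `linearity` column.
#' @export
baseline_segment <- function(cloud, height_quantile = 0.4, radius = 0.03,
                             linearity_threshold = 0.55) {
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n < 10) abort("baseline_segment needs at least 10 points")
  coords <- cloud_coords(cloud)
  if (max(apply(coords, 2, function(v) diff(range(v)))) == 0) {
    warn("degenerate (all-coincident) cloud; labeling everything stem")
    out <- cloud
    out$label <- 0L
    out$linearity <- 0
    return(as_point_cloud(out))
  }
  nbrs <- cpp_radius_search(coords, coords, radius)
  lin <- vapply(seq_len(n), function(i) {
    nb <- coords[nbrs[[i]], , drop = FALSE]
    if (nrow(nb) < 3) return(0)
    cv <- crossprod(sweep(nb, 2, colMeans(nb))) / nrow(nb)
    ev <- sym3x3_eigenvalues(cv[1, 1], cv[2, 2], cv[3, 3], cv[1, 2],
                             cv[1, 3], cv[2, 3])
    if (ev$l1 > 1e-24) (ev$l1 - ev$l2) / ev$l1 else 0
  }, numeric(1))
  thr_z <- if (height_quantile <= 0) -Inf else
    unname(quantile(cloud$z, height_quantile))
  out <- cloud
  out$label <- as.integer(lin >= linearity_threshold & cloud$z > thr_z)
  out$linearity <- lin
  as_point_cloud(out)
}

# analytic eigenvalues of symmetric 3x3 matrices (trigonometric method),
# vectorised; returns l1 >= l2 >= l3
sym3x3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- (b11^2 + b22^2 + b33^2 + 2 * (a12^2 + a13^2 + a23^2)) / 6
  p <- sqrt(pmax(p2, 0))
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  list(l1 = l1, l2 = l2, l3 = l3)
}
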
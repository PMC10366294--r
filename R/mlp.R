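#' Training control parameters for the capsule MLP
#'
#' Collects the hyperparameters of [capsule_mlp()]. Defaults follow the
#' training protocol used throughout the package: three hidden layers of
#' 128 rectified linear units, Adam with initial learning rate 0.001,
#' mini-batches of 128, 10% validation split, dropout rate 0.3, and a
#' plateau schedule that divides the learning rate by 10 after `patience`
#' validation epochs without improvement and stops after `stop_patience`
#' further stagnant epochs, returning the parameters of the best
#' validation epoch.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of samples held out for validation.
#' @param dropout Dropout rate on hidden activations (0 disables).
#' @param hidden Integer vector of hidden-layer widths.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Stagnant validation epochs before the learning rate is
#'   multiplied by `lr_factor`.
#' @param stop_patience Additional stagnant epochs (beyond `patience`)
#'   before training terminates.
#' @param lr_factor Learning-rate reduction factor at a plateau.
#' @param lambda Weight of the regression loss relative to the
#'   cross-entropy classification loss in the combined objective.
#' @param batch_norm Apply batch normalisation before each hidden
#'   activation.
#' @param seed Integer seed controlling initialisation, the validation
#'   split, batch shuffling and dropout; training is a deterministic
#'   function of the data and this seed.
#' @param two_networks Train two independent networks (one per head)
#'   instead of one shared trunk with two output heads.
#' @return A list of class `"mlp_control"`.
#' @export
mlp_control <- function(learning_rate = 0.001, batch_size = 128,
                        validation_fraction = 0.10, dropout = 0.3,
                        hidden = c(128, 128, 128), max_epochs = 1500,
                        patience = 10, stop_patience = 20, lr_factor = 0.1,
                        lambda = 1, batch_norm = TRUE, seed = 1,
                        two_networks = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1,
            dropout >= 0, dropout < 1, length(hidden) >= 1, all(hidden >= 1),
            max_epochs >= 1, patience >= 1, stop_patience >= 1,
            lr_factor > 0, lr_factor < 1, lambda >= 0)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 validation_fraction = validation_fraction,
                 dropout = dropout, hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 stop_patience = as.integer(stop_patience),
                 lr_factor = lr_factor, lambda = lambda,
                 batch_norm = isTRUE(batch_norm), seed = seed,
                 two_networks = isTRUE(two_networks)),
            class = "mlp_control")
}

# ---- low-level network arithmetic -------------------------------------

rowmat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# He-style initialisation of the trunk and both heads.
init_network <- function(d_in, hidden, batch_norm) {
  sizes <- c(d_in, hidden)
  layers <- lapply(seq_along(hidden), function(l) {
    k_in <- sizes[l]; k_out <- sizes[l + 1]
    lay <- list(W = matrix(stats::rnorm(k_out * k_in, sd = sqrt(2 / k_in)),
                           k_out, k_in),
                b = numeric(k_out))
    if (batch_norm) {
      lay$gamma <- rep(1, k_out); lay$beta <- numeric(k_out)
      lay$run_mean <- numeric(k_out); lay$run_var <- rep(1, k_out)
    }
    lay
  })
  k <- sizes[length(sizes)]
  list(layers = layers,
       cls = list(W = matrix(stats::rnorm(3 * k, sd = sqrt(2 / k)), 3, k),
                  b = numeric(3)),
       reg = list(W = matrix(stats::rnorm(2 * k, sd = sqrt(2 / k)), 2, k),
                  b = numeric(2)))
}

#' Feed-forward pass of a capsule MLP
#'
#' Low-level forward evaluation: per hidden layer an affine map
#' (weights times inputs plus bias), batch normalisation when the layer
#' carries normalisation parameters, ReLU activation, and (in training
#' mode only) dropout; the classification head applies a numerically
#' stabilised softmax and the regression head is linear. In inference mode
#' the frozen running batch statistics are used and no dropout is applied,
#' so the map is a pure function of its input.
#'
#' @param net A network parameter list (as stored in a fitted
#'   [capsule_mlp()] under `$net`, or hand-built with the same structure:
#'   `layers` with `W`, `b` and optional `gamma`/`beta`/`run_mean`/
#'   `run_var`, plus `cls` and `reg` heads).
#' @param X Input matrix, one feature vector per row (a single vector is
#'   accepted).
#' @param training Training mode: use batch statistics and apply dropout
#'   with rate `dropout`.
#' @param dropout Dropout rate used when `training = TRUE`.
#' @return List with `probs` (rows sum to one), `logits`, and `reg` (raw
#'   regression outputs, standardised units).
#' @export
mlp_forward <- function(net, X, training = FALSE, dropout = 0) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(net$layers[[1]]$W))
    stop(sprintf("input length %d does not match the network input size %d",
                 ncol(X), ncol(net$layers[[1]]$W)))
  H <- X
  n <- nrow(X)
  for (lay in net$layers) {
    Z <- H %*% t(lay$W) + rowmat(lay$b, n)
    if (!is.null(lay$gamma)) {
      mu <- if (training) colMeans(Z) else lay$run_mean
      va <- if (training) colMeans(Z^2) - mu^2 else lay$run_var
      Z <- (Z - rowmat(mu, n)) / rowmat(sqrt(va + 1e-5), n)
      Z <- Z * rowmat(lay$gamma, n) + rowmat(lay$beta, n)
    }
    H <- pmax(Z, 0)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= dropout, n) / (1 - dropout)
      H <- H * mask
    }
  }
  logits <- H %*% t(net$cls$W) + rowmat(net$cls$b, n)
  list(probs = softmax(logits), logits = logits,
       reg = H %*% t(net$reg$W) + rowmat(net$reg$b, n))
}

# Cross-entropy and summed-square losses of raw head outputs against a
# class index vector and a standardised target matrix; means over the batch.
mlp_losses <- function(probs, reg, z_idx, y) {
  p_true <- pmax(probs[cbind(seq_along(z_idx), z_idx)], 1e-12)
  list(cls = mean(-log(p_true)),
       reg = mean(rowSums((y - reg)^2)))
}

# One forward + backward pass on a mini-batch; returns gradients and losses.
# w_cls / w_reg weight the two heads in the combined objective.
mlp_backward <- function(net, X, z_idx, y, dropout, w_cls, w_reg) {
  n <- nrow(X)
  nl <- length(net$layers)
  cache <- vector("list", nl)
  H <- X
  for (l in seq_len(nl)) {
    lay <- net$layers[[l]]
    cc <- list(Hin = H)
    Z <- H %*% t(lay$W) + rowmat(lay$b, n)
    if (!is.null(lay$gamma)) {
      mu <- colMeans(Z); va <- colMeans(Z^2) - mu^2
      sd_ <- sqrt(va + 1e-5)
      Zhat <- (Z - rowmat(mu, n)) / rowmat(sd_, n)
      cc$Zhat <- Zhat; cc$sd <- sd_; cc$mu <- mu; cc$va <- va
      A <- Zhat * rowmat(lay$gamma, n) + rowmat(lay$beta, n)
    } else A <- Z
    cc$A <- A
    H <- pmax(A, 0)
    if (dropout > 0) {
      mask <- matrix(stats::runif(length(H)) >= dropout, n) / (1 - dropout)
      H <- H * mask
      cc$mask <- mask
    }
    cc$Hout <- H
    cache[[l]] <- cc
  }
  logits <- H %*% t(net$cls$W) + rowmat(net$cls$b, n)
  probs <- softmax(logits)
  reg <- H %*% t(net$reg$W) + rowmat(net$reg$b, n)
  losses <- mlp_losses(probs, reg, z_idx, y)

  onehot <- matrix(0, n, 3); onehot[cbind(seq_len(n), z_idx)] <- 1
  dlogits <- w_cls * (probs - onehot) / n
  dreg <- w_reg * 2 * (reg - y) / n
  grads <- list(cls = list(W = crossprod(dlogits, H), b = colSums(dlogits)),
                reg = list(W = crossprod(dreg, H), b = colSums(dreg)),
                layers = vector("list", nl))
  dH <- dlogits %*% net$cls$W + dreg %*% net$reg$W
  for (l in rev(seq_len(nl))) {
    lay <- net$layers[[l]]; cc <- cache[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dA <- dH * (cc$A > 0)
    g <- list()
    if (!is.null(lay$gamma)) {
      g$gamma <- colSums(dA * cc$Zhat)
      g$beta <- colSums(dA)
      dZhat <- dA * rowmat(lay$gamma, n)
      # batch-statistics backward pass
      dZ <- (dZhat - rowmat(colMeans(dZhat), n) -
               cc$Zhat * rowmat(colMeans(dZhat * cc$Zhat), n)) /
        rowmat(cc$sd, n)
      g$batch_mean <- cc$mu; g$batch_var <- cc$va
    } else dZ <- dA
    g$W <- crossprod(dZ, cc$Hin)
    g$b <- colSums(dZ)
    grads$layers[[l]] <- g
    if (l > 1) dH <- dZ %*% lay$W
  }
  list(grads = grads, losses = losses)
}

# ---- Adam optimiser over the nested parameter list --------------------

adam_state <- function() list(t = 0, m = list(), v = list())

# Applies one Adam update; parameters addressed by flat names.
adam_step <- function(net, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(slot, par, g) {
    m <- state$m[[slot]]; v <- state$v[[slot]]
    if (is.null(m)) { m <- par * 0; v <- par * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    state$m[[slot]] <<- m; state$v[[slot]] <<- v
    mh <- m / (1 - b1^state$t); vh <- v / (1 - b2^state$t)
    par - lr * mh / (sqrt(vh) + eps)
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(net$layers[[l]][[nm]]))
        net$layers[[l]][[nm]] <- upd(paste0("L", l, nm),
                                     net$layers[[l]][[nm]],
                                     grads$layers[[l]][[nm]])
    }
    g <- grads$layers[[l]]
    if (!is.null(g$batch_mean)) {
      net$layers[[l]]$run_mean <-
        0.9 * net$layers[[l]]$run_mean + 0.1 * g$batch_mean
      net$layers[[l]]$run_var <-
        0.9 * net$layers[[l]]$run_var + 0.1 * g$batch_var
    }
  }
  for (hd in c("cls", "reg")) {
    net[[hd]]$W <- upd(paste0(hd, "W"), net[[hd]]$W, grads[[hd]]$W)
    net[[hd]]$b <- upd(paste0(hd, "b"), net[[hd]]$b, grads[[hd]]$b)
  }
  list(net = net, state = state)
}

# ---- training ----------------------------------------------------------

# Core training routine over design matrix X, class indices z, raw targets
# y (n x 2); returns the best-validation network plus history.
train_network <- function(X, z_idx, y, control, w_cls = 1, w_reg = NULL) {
  if (is.null(w_reg)) w_reg <- control$lambda
  n <- nrow(X)
  n_val <- max(1L, round(control$validation_fraction * n))
  if (n - n_val < control$batch_size)
    stop("dataset smaller than one mini-batch after the validation split")
  with_seed(control$seed, {
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    y_mean <- colMeans(y[tr_idx, , drop = FALSE])
    y_sd <- apply(y[tr_idx, , drop = FALSE], 2, stats::sd)
    y_sd[y_sd < 1e-12] <- 1
    ys <- sweep(sweep(y, 2, y_mean), 2, y_sd, "/")
    net <- init_network(ncol(X), control$hidden, control$batch_norm)
    state <- adam_state()
    lr <- control$learning_rate
    best <- list(loss = Inf, net = net, epoch = 0L)
    stagnant <- 0L
    reduced_at <- integer(0)
    hist <- matrix(NA_real_, control$max_epochs, 3,
                   dimnames = list(NULL, c("train_loss", "val_loss", "lr")))
    epoch <- 0L
    Xv <- X[val_idx, , drop = FALSE]
    while (epoch < control$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample(tr_idx)
      tl <- 0; nb <- 0L
      for (s in seq(1, length(ord), by = control$batch_size)) {
        bi <- ord[s:min(s + control$batch_size - 1L, length(ord))]
        if (length(bi) < 2L) next  # batch statistics need >= 2 samples
        bw <- mlp_backward(net, X[bi, , drop = FALSE], z_idx[bi],
                           ys[bi, , drop = FALSE], control$dropout,
                           w_cls, w_reg)
        if (!is.finite(bw$losses$cls) || !is.finite(bw$losses$reg))
          stop("non-finite training loss at epoch ", epoch)
        st <- adam_step(net, bw$grads, state, lr)
        net <- st$net; state <- st$state
        tl <- tl + w_cls * bw$losses$cls + w_reg * bw$losses$reg
        nb <- nb + 1L
      }
      fv <- mlp_forward(net, Xv)
      lv <- mlp_losses(fv$probs, fv$reg, z_idx[val_idx],
                       ys[val_idx, , drop = FALSE])
      vloss <- w_cls * lv$cls + w_reg * lv$reg
      hist[epoch, ] <- c(tl / max(nb, 1L), vloss, lr)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, net = net, epoch = epoch)
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant == control$patience) {
          lr <- lr * control$lr_factor
          reduced_at <- c(reduced_at, epoch)
        }
        if (stagnant >= control$patience + control$stop_patience) break
      }
    }
    list(net = best$net, best_epoch = best$epoch, val_loss = best$loss,
         epochs_run = epoch, lr_reductions = reduced_at,
         history = data.frame(epoch = seq_len(epoch),
                              hist[seq_len(epoch), , drop = FALSE]),
         y_mean = y_mean, y_sd = y_sd,
         val_idx = val_idx)
  })
}

#' Fit the capsule characterisation MLP
#'
#' Trains the multilayer perceptron that maps a capsule's footprint
#' feature vector to (i) the probabilities of the three membrane
#' constitutive-law classes, through a softmax classification head, and
#' (ii) the two capillary numbers `Ca^Ks` and `Ca^Gs`, through a linear
#' regression head — one shared rectified-linear trunk feeding both heads,
#' trained with the combined loss `L = L_cls + lambda * L_reg`, where
#' `L_cls` is the cross-entropy of the predicted class probabilities and
#' `L_reg` the squared error summed over the two (standardised) targets,
#' each averaged over the mini-batch. Optimisation uses Adam with
#' mini-batches, batch normalisation and dropout; a held-out validation
#' split drives a reduce-on-plateau learning-rate schedule and early
#' stopping, and the parameters of the best validation epoch are returned.
#' Regression targets are standardised to zero mean and unit variance over
#' the training split (the statistics travel with the fit and predictions
#' are de-standardised automatically); without this the raw capillary
#' numbers, of order 0.02-0.21, would make the square loss negligible
#' against the cross-entropy.
#'
#' @param dataset A `capsule_dataset` from [generate_dataset()], or a list
#'   with `x` (matrix of feature vectors), `kind` (character law labels)
#'   and `y` (two-column matrix of `ca_ks`, `ca_gs`).
#' @param control Hyperparameters; see [mlp_control()].
#' @return An object of class `"capsule_mlp"`: list with `net` (trained
#'   weights, biases and frozen batch statistics), `y_mean`/`y_sd`
#'   (target standardisation), `classes`, `history` (per-epoch losses),
#'   `best_epoch`, `val_loss`, `control` and the dataset `manifest`. With
#'   `two_networks = TRUE`, `net` is replaced by `net_cls` and `net_reg`.
#' @seealso [predict.capsule_mlp()], [mape()], [run_recovery_study()]
#' @examples
#' \donttest{
#' ds <- generate_dataset(n = 120, n_nodes = 20, seed = 1)
#' fit <- capsule_mlp(ds, mlp_control(batch_size = 32, max_epochs = 60,
#'                                    seed = 1))
#' predict(fit, ds)[1:3, ]
#' }
#' @export
capsule_mlp <- function(dataset, control = mlp_control()) {
  stopifnot(inherits(control, "mlp_control"))
  d <- as_training_data(dataset)
  fit <- list(classes = law_kinds, control = control,
              input_size = ncol(d$x),
              manifest = if (inherits(dataset, "capsule_dataset"))
                dataset$manifest else NULL)
  if (control$two_networks) {
    c1 <- control; c1$seed <- control$seed
    t1 <- train_network(d$x, d$z, d$y, c1, w_cls = 1, w_reg = 0)
    c2 <- control; c2$seed <- control$seed + 1
    t2 <- train_network(d$x, d$z, d$y, c2, w_cls = 0, w_reg = 1)
    fit$net_cls <- t1$net; fit$net_reg <- t2$net
    fit$y_mean <- t2$y_mean; fit$y_sd <- t2$y_sd
    fit$history <- t2$history; fit$best_epoch <- t2$best_epoch
    fit$val_loss <- t2$val_loss; fit$epochs_run <- t2$epochs_run
  } else {
    tr <- train_network(d$x, d$z, d$y, control)
    fit$net <- tr$net
    fit$y_mean <- tr$y_mean; fit$y_sd <- tr$y_sd
    fit$history <- tr$history; fit$best_epoch <- tr$best_epoch
    fit$val_loss <- tr$val_loss; fit$epochs_run <- tr$epochs_run
    fit$lr_reductions <- tr$lr_reductions
  }
  structure(fit, class = "capsule_mlp")
}

# Coerce the accepted dataset forms into x / z / y.
as_training_data <- function(dataset) {
  if (inherits(dataset, "capsule_dataset")) {
    x <- do.call(rbind, lapply(dataset$samples, `[[`, "vector"))
    kind <- vapply(dataset$samples, `[[`, "", "kind")
    y <- cbind(vapply(dataset$samples, `[[`, 0, "ca_ks"),
               vapply(dataset$samples, `[[`, 0, "ca_gs"))
  } else if (is.list(dataset) && !is.null(dataset$x)) {
    x <- as.matrix(dataset$x)
    kind <- as.character(dataset$kind)
    y <- as.matrix(dataset$y)
  } else stop("'dataset' must be a capsule_dataset or an x/kind/y list")
  if (nrow(x) < 2) stop("dataset must contain at least two samples")
  z <- match(vapply(kind, normalize_law_kind, ""), law_kinds)
  if (anyNA(z)) stop("unknown law labels in dataset")
  colnames(y) <- c("ca_ks", "ca_gs")
  list(x = x, z = z, y = y)
}

#' Predict law class and capillary numbers for new profiles
#'
#' Runs the fitted network in inference mode (frozen batch statistics, no
#' dropout — a pure feed-forward map) on one or more feature vectors. The
#' law class is the highest-probability head output; the regressed
#' capillary numbers are de-standardised with the stored training
#' statistics and floored at a small positive value. When a
#' [flow_condition()] is supplied, the membrane moduli `Gs = mu U / Ca^Gs`
#' and `Ks = mu U / Ca^Ks` are attached.
#'
#' @param object A fitted [capsule_mlp()].
#' @param newdata A `capsule_dataset`, a matrix of feature vectors (one
#'   per row), a single feature vector, or a `capsule_profile`.
#' @param flow Optional [flow_condition()] for converting capillary
#'   numbers into moduli.
#' @param ... Unused.
#' @return Data frame with one row per input: class probabilities
#'   (`prob_NH`, `prob_SK`, `prob_HK`), `kind`, `ca_ks`, `ca_gs`, and
#'   `Gs`, `Ks` when `flow` is given.
#' @export
predict.capsule_mlp <- function(object, newdata, flow = NULL, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$input_size)
    stop(sprintf("expected feature vectors of length %d, got %d",
                 object$input_size, ncol(X)))
  if (object$control$two_networks) {
    probs <- mlp_forward(object$net_cls, X)$probs
    reg <- mlp_forward(object$net_reg, X)$reg
  } else {
    fw <- mlp_forward(object$net, X)
    probs <- fw$probs; reg <- fw$reg
  }
  ca <- sweep(sweep(reg, 2, object$y_sd, "*"), 2, object$y_mean, "+")
  ca <- pmax(ca, 1e-6)
  out <- data.frame(prob_NH = probs[, 1], prob_SK = probs[, 2],
                    prob_HK = probs[, 3],
                    kind = object$classes[max.col(probs,
                                                  ties.method = "first")],
                    ca_ks = ca[, 1], ca_gs = ca[, 2])
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "flow_condition"))
    out$Gs <- flow$mu * flow$U / out$ca_gs
    out$Ks <- flow$mu * flow$U / out$ca_ks
  }
  rownames(out) <- NULL
  out
}

as_feature_matrix <- function(newdata) {
  if (inherits(newdata, "capsule_dataset"))
    return(do.call(rbind, lapply(newdata$samples, `[[`, "vector")))
  if (inherits(newdata, "capsule_profile"))
    return(matrix(to_feature_vector(newdata), nrow = 1))
  if (is.null(dim(newdata))) return(matrix(newdata, nrow = 1))
  as.matrix(newdata)
}

#' @export
print.capsule_mlp <- function(x, ...) {
  cat(sprintf(
    "capsule MLP: %d -> %s -> (3 classes + 2 capillary numbers)\n",
    x$input_size, paste(x$control$hidden, collapse = "-")))
  cat(sprintf(
    "  trained %d epochs (best %d), validation loss %.4g%s\n",
    x$epochs_run, x$best_epoch, x$val_loss,
    if (x$control$two_networks) " [two independent networks]" else ""))
  invisible(x)
}

#' @export
summary.capsule_mlp <- function(object, ...) {
  print(object)
  h <- object$history
  cat(sprintf("  final train loss %.4g, lr at stop %.1e\n",
              h$train_loss[nrow(h)], h$lr[nrow(h)]))
  np <- sum(vapply(coef(object), length, 0L))
  cat(sprintf("  %d trainable parameters, dropout %.2g, lambda %.2g\n",
              np, object$control$dropout, object$control$lambda))
  invisible(object)
}

#' Extract network weights
#'
#' @param object A fitted [capsule_mlp()].
#' @param ... Unused.
#' @return Named list of weight/bias (and batch-norm scale/shift) arrays.
#' @export
coef.capsule_mlp <- function(object, ...) {
  net <- if (object$control$two_networks) object$net_reg else object$net
  out <- list()
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    for (nm in c("W", "b", "gamma", "beta"))
      if (!is.null(lay[[nm]])) out[[paste0("layer", l, "_", nm)]] <- lay[[nm]]
  }
  out$cls_W <- net$cls$W; out$cls_b <- net$cls$b
  out$reg_W <- net$reg$W; out$reg_b <- net$reg$b
  out
}

#' Plot training and validation loss curves
#'
#' @param x A fitted [capsule_mlp()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.capsule_mlp <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = c(1, 2), xlab = "epoch",
                    ylab = "combined loss", log = "y", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1:2,
                   col = c(1, 2), bty = "n")
  invisible(x)
}

# ---- serialisation ------------------------------------------------------

#' Save or load a fitted capsule MLP as JSON
#'
#' The whole fit — layer shapes, weights, batch statistics, target
#' standardisation, control settings and training manifest — is written to
#' a single self-describing JSON file.
#'
#' @param model A fitted [capsule_mlp()].
#' @param path Path of the JSON file.
#' @return `write_capsule_mlp()` returns `path` invisibly;
#'   `read_capsule_mlp()` the restored `capsule_mlp`.
#' @export
write_capsule_mlp <- function(model, path) {
  stopifnot(inherits(model, "capsule_mlp"))
  payload <- unclass(model)
  payload$control <- unclass(payload$control)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_capsule_mlp
#' @export
read_capsule_mlp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  p$history <- as.data.frame(p$history)
  fix_net <- function(net) {
    net$layers <- lapply(net$layers, function(lay) {
      lay$W <- as.matrix(lay$W)
      lay
    })
    net$cls$W <- as.matrix(net$cls$W)
    net$reg$W <- as.matrix(net$reg$W)
    net
  }
  for (nm in intersect(c("net", "net_cls", "net_reg"), names(p)))
    p[[nm]] <- fix_net(p[[nm]])
  p$control <- do.call(mlp_control, p$control)
  structure(p, class = "capsule_mlp")
}
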
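# Residual-learning convolutional denoiser used for grid removal.
# The network predicts the grid component v from a noisy observation
# y = x + v; subtracting the predicted residual yields the clean trace.
# Layers: conv+ReLU, (depth-2) x conv+batchnorm+ReLU, single-filter conv.
# Convolution kernels live in src/conv.cpp; everything else is vectorized R.

#' Denoiser architecture and training specification
#'
#' The full preset mirrors the grid-removal architecture (17 layers, 64
#' filters of 7 x 7, residual output, early stopping within 30 epochs). The
#' desk preset is a reduced architecture for CPU-scale experiments and the
#' test suite (2000 patches, few epochs) and learns periodic grid residuals
#' comfortably.
#'
#' @param depth number of conv layers (>= 3).
#' @param filters filters per hidden layer.
#' @param kernel odd kernel side.
#' @param epochs maximum training epochs (early stopping).
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (validation loss).
#' @param val_fraction fraction of pairs held out for validation.
#' @param seed integer seed (init + shuffling).
#' @param preset `"full"` or `"desk"` shortcut overriding
#'   depth/filters/kernel/epochs.
#' @return validated list of class `"DenoiserSpec"`.
#' @export
denoiserSpec <- function(depth = 17, filters = 64, kernel = 7, epochs = 30,
                         batch_size = 128, lr = 1e-3, patience = 5,
                         val_fraction = 0.1, seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "desk"))
    if (preset == "desk") {
      depth <- 4; filters <- 12; kernel <- 5; epochs <- 5
      batch_size <- 8; lr <- 1e-2
    }
  }
  if (depth < 3) stop("depth must be at least 3")
  if (kernel %% 2 != 1) stop("kernel must be odd")
  structure(list(depth = as.integer(depth), filters = as.integer(filters),
                 kernel = as.integer(kernel), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = seed),
            class = "DenoiserSpec")
}

# He-style initialization; the final layer starts at zero so the residual
# prediction (and hence the denoised output) begins exactly at the identity
initDenoiser <- function(spec) {
  layers <- vector("list", spec$depth)
  for (l in seq_len(spec$depth)) {
    cin <- if (l == 1L) 1L else spec$filters
    cout <- if (l == spec$depth) 1L else spec$filters
    fan_in <- spec$kernel^2 * cin
    W <- if (l == spec$depth)
      array(0, dim = c(spec$kernel, spec$kernel, cin, cout))
    else
      array(stats::rnorm(spec$kernel^2 * cin * cout, 0, sqrt(2 / fan_in)),
            dim = c(spec$kernel, spec$kernel, cin, cout))
    layers[[l]] <- list(W = W, b = numeric(cout))
    if (l > 1L && l < spec$depth) {
      layers[[l]]$gamma <- rep(1, cout)
      layers[[l]]$beta <- numeric(cout)
      layers[[l]]$rmean <- numeric(cout)
      layers[[l]]$rvar <- rep(1, cout)
    }
  }
  layers
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# x: (H, W, C, N). Returns list(out, cache) in training mode, list(out) in
# eval mode. Updates running stats by reference semantics via return value.
denoiserForward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    ly <- layers[[l]]
    z <- conv2d_forward(x, ly$W, ly$b)
    cache <- list(x_in = x)
    has_bn <- !is.null(ly$gamma)
    if (has_bn) {
      d <- dim(z); C <- d[3L]
      zm <- matrix(aperm(z, c(1L, 2L, 4L, 3L)), ncol = C)
      if (training) {
        mu <- colMeans(zm)
        va <- colMeans(zm^2) - mu^2
        layers[[l]]$rmean <- BN_MOMENTUM * ly$rmean + (1 - BN_MOMENTUM) * mu
        layers[[l]]$rvar <- BN_MOMENTUM * ly$rvar + (1 - BN_MOMENTUM) * va
      } else {
        mu <- ly$rmean; va <- ly$rvar
      }
      istd <- 1 / sqrt(va + BN_EPS)
      zhat <- sweep(sweep(zm, 2L, mu), 2L, istd, `*`)
      zn <- sweep(sweep(zhat, 2L, ly$gamma, `*`), 2L, ly$beta, `+`)
      cache$zhat <- zhat; cache$istd <- istd
      z <- aperm(array(zn, dim = d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
    }
    if (l < length(layers)) {
      cache$pre_relu <- z
      z <- z * (z > 0)
    }
    caches[[l]] <- cache
    x <- z
  }
  list(out = x, caches = caches, layers = layers)
}

# Backward pass; returns per-layer gradients (same structure as layers).
denoiserBackward <- function(layers, caches, grad_out) {
  grads <- vector("list", length(layers))
  g <- grad_out
  for (l in rev(seq_along(layers))) {
    ly <- layers[[l]]; cache <- caches[[l]]
    if (l < length(layers)) g <- g * (cache$pre_relu > 0)
    if (!is.null(ly$gamma)) {
      d <- dim(g); C <- d[3L]
      gm <- matrix(aperm(g, c(1L, 2L, 4L, 3L)), ncol = C)
      m <- nrow(gm)
      gbeta <- colSums(gm)
      ggamma <- colSums(gm * cache$zhat)
      gzh <- sweep(gm, 2L, ly$gamma, `*`)
      gz <- sweep(gzh - matrix(colMeans(gzh), m, C, byrow = TRUE) -
                    cache$zhat * matrix(colMeans(gzh * cache$zhat), m, C,
                                        byrow = TRUE),
                  2L, cache$istd, `*`)
      g <- aperm(array(gz, dim = d[c(1L, 2L, 4L, 3L)]), c(1L, 2L, 4L, 3L))
      grads[[l]]$gamma <- ggamma
      grads[[l]]$beta <- gbeta
    }
    bk <- conv2d_backward(cache$x_in, ly$W, g)
    grads[[l]]$W <- bk$grad_weights
    grads[[l]]$b <- bk$grad_bias
    g <- bk$grad_input
  }
  grads
}

adamInit <- function(layers) {
  lapply(layers, function(ly) {
    st <- list(mW = array(0, dim(ly$W)), vW = array(0, dim(ly$W)),
               mb = numeric(length(ly$b)), vb = numeric(length(ly$b)))
    if (!is.null(ly$gamma)) {
      st$mg <- numeric(length(ly$gamma)); st$vg <- st$mg
      st$mbeta <- st$mg; st$vbeta <- st$mg
    }
    st
  })
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr * corr * m / (sqrt(v) + eps), m = m, v = v)
  }
  for (l in seq_along(layers)) {
    u <- upd(layers[[l]]$W, grads[[l]]$W, state[[l]]$mW, state[[l]]$vW)
    layers[[l]]$W <- u$p; state[[l]]$mW <- u$m; state[[l]]$vW <- u$v
    u <- upd(layers[[l]]$b, grads[[l]]$b, state[[l]]$mb, state[[l]]$vb)
    layers[[l]]$b <- u$p; state[[l]]$mb <- u$m; state[[l]]$vb <- u$v
    if (!is.null(layers[[l]]$gamma)) {
      u <- upd(layers[[l]]$gamma, grads[[l]]$gamma, state[[l]]$mg,
               state[[l]]$vg)
      layers[[l]]$gamma <- u$p; state[[l]]$mg <- u$m; state[[l]]$vg <- u$v
      u <- upd(layers[[l]]$beta, grads[[l]]$beta, state[[l]]$mbeta,
               state[[l]]$vbeta)
      layers[[l]]$beta <- u$p; state[[l]]$mbeta <- u$m
      state[[l]]$vbeta <- u$v
    }
  }
  list(layers = layers, state = state)
}

# stack a (H, W, N) patch array into the (H, W, 1, N) network layout
asNetInput <- function(p) {
  d <- dim(p)
  array(p, dim = c(d[1L], d[2L], 1L, d[3L]))
}

#' Train the residual grid-removal denoiser
#'
#' Minimizes the residual loss
#' `l(Theta) = 1/(2N) sum_i || R(y_i; Theta) - (y_i - x_i) ||_F^2`
#' with Adam, early-stopping on a validation split. Pairs are single-channel
#' patches scaled to `[0, 1]`: `noisy` contains the gridded observations
#' `y`, `clean` the grid-free targets `x`.
#'
#' @param pairs list with `noisy` and `clean`, each an `H x W x N` array.
#' @param spec [denoiserSpec()] result.
#' @param verbose print per-epoch losses.
#' @return model of class `"ECGDenoiser"`: layer weights, spec and the
#'   training history (train/validation loss per epoch).
#' @export
trainDenoiser <- function(pairs, spec = denoiserSpec(preset = "desk"),
                          verbose = FALSE) {
  stopifnot(inherits(spec, "DenoiserSpec"))
  y <- pairs$noisy; x <- pairs$clean
  if (is.null(y) || is.null(x) || !identical(dim(y), dim(x)))
    stop("pairs$noisy and pairs$clean must be arrays of identical shape")
  N <- dim(y)[3L]
  withSeed(spec$seed, {
    layers <- initDenoiser(spec)
    state <- adamInit(layers)
    idx <- sample.int(N)
    n_val <- max(1L, round(spec$val_fraction * N))
    val_idx <- idx[seq_len(n_val)]
    tr_idx <- idx[-seq_len(n_val)]
    v_res <- asNetInput(y[, , val_idx, drop = FALSE] -
                          x[, , val_idx, drop = FALSE])
    v_in <- asNetInput(y[, , val_idx, drop = FALSE])
    history <- data.frame(epoch = integer(0), train = numeric(0),
                          val = numeric(0))
    best_val <- Inf; best_layers <- layers; bad <- 0L; t_step <- 0L
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(tr_idx)
      tr_loss <- 0; n_seen <- 0L
      for (start in seq(1L, length(ord), by = spec$batch_size)) {
        bi <- ord[start:min(start + spec$batch_size - 1L, length(ord))]
        yb <- asNetInput(y[, , bi, drop = FALSE])
        vb <- asNetInput(y[, , bi, drop = FALSE] - x[, , bi, drop = FALSE])
        fw <- denoiserForward(layers, yb, training = TRUE)
        layers <- fw$layers
        err <- fw$out - vb
        nb <- length(bi)
        loss <- sum(err^2) / (2 * nb)
        grads <- denoiserBackward(layers, fw$caches, err / nb)
        t_step <- t_step + 1L
        st <- adamStep(layers, grads, state, spec$lr, t_step)
        layers <- st$layers; state <- st$state
        tr_loss <- tr_loss + loss * nb; n_seen <- n_seen + nb
      }
      pv <- denoiserForward(layers, v_in, training = FALSE)$out
      val_loss <- sum((pv - v_res)^2) / (2 * n_val)
      history <- rbind(history,
                       data.frame(epoch = ep, train = tr_loss / n_seen,
                                  val = val_loss))
      if (verbose)
        message(sprintf("epoch %d: train %.3g val %.3g", ep,
                        tr_loss / n_seen, val_loss))
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best_layers <- layers; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= spec$patience) break
      }
    }
    structure(list(layers = best_layers, spec = spec, history = history),
              class = "ECGDenoiser")
  })
}

#' Predict grid residuals with a trained denoiser
#'
#' @param model `"ECGDenoiser"` from [trainDenoiser()].
#' @param patches `H x W x N` array in `[0, 1]`.
#' @param batch prediction batch size.
#' @return `H x W x N` array of predicted residuals `R(y)`.
#' @export
predictResidual <- function(model, patches, batch = 256L) {
  stopifnot(inherits(model, "ECGDenoiser"))
  d <- dim(patches)
  out <- array(0, dim = d)
  for (start in seq(1L, d[3L], by = batch)) {
    bi <- start:min(start + batch - 1L, d[3L])
    p <- denoiserForward(model$layers,
                         asNetInput(patches[, , bi, drop = FALSE]),
                         training = FALSE)$out
    out[, , bi] <- array(p, dim = c(d[1L], d[2L], length(bi)))
  }
  out
}

#' Save/load a denoiser model as JSON
#'
#' Single-file serialization of the layer weights plus the architecture
#' sidecar, portable across platforms.
#'
#' @param model `"ECGDenoiser"`.
#' @param path file path.
#' @return `loadDenoiser` returns the model; `saveDenoiser` the path,
#'   invisibly.
#' @export
saveDenoiser <- function(model, path) {
  stopifnot(inherits(model, "ECGDenoiser"))
  payload <- list(
    spec = unclass(model$spec),
    layers = lapply(model$layers, function(ly) {
      out <- list(W = as.numeric(ly$W), dimW = dim(ly$W), b = ly$b)
      for (f in c("gamma", "beta", "rmean", "rvar"))
        if (!is.null(ly[[f]])) out[[f]] <- ly[[f]]
      out
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveDenoiser
#' @export
loadDenoiser <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(denoiserSpec, payload$spec[c("depth", "filters", "kernel",
                                               "epochs", "batch_size", "lr",
                                               "patience", "val_fraction",
                                               "seed")])
  layers <- lapply(seq_len(nrow_or_len(payload$layers)), function(i) {
    ly <- extractLayer(payload$layers, i)
    out <- list(W = array(ly$W, dim = ly$dimW), b = as.numeric(ly$b))
    for (f in c("gamma", "beta", "rmean", "rvar"))
      if (!is.null(ly[[f]])) out[[f]] <- as.numeric(ly[[f]])
    out
  })
  structure(list(layers = layers, spec = spec, history = NULL),
            class = "ECGDenoiser")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extractLayer <- function(layers, i) {
  if (is.data.frame(layers)) lapply(layers, function(col) col[[i]])
  else layers[[i]]
}

#' Toy grid patch pairs for desk-scale denoiser training
#'
#' Generates single-channel 30 x 30 patch pairs in `[0, 1]`: clean patches
#' contain a smooth light background plus a random dark trace-like curve;
#' the noisy version additionally carries a periodic grid-line pattern
#' (random pitch, phase, orientation weight and intensity). About one patch
#' in ten is grid-free so the trained residual stays near zero on clean
#' input. Emulates the gridded/grid-free render pairs used for full-scale
#' training.
#'
#' @param n number of pairs.
#' @param size patch side in px.
#' @param seed integer seed.
#' @return list with `noisy` and `clean` arrays (`size x size x n`).
#' @export
makeGridPatchPairs <- function(n, size = 30L, seed = 1) {
  withSeed(seed, {
    clean <- array(0, dim = c(size, size, n))
    noisy <- clean
    xs <- seq_len(size)
    for (i in seq_len(n)) {
      bg <- 1 - stats::runif(1, 0, 0.05)
      x <- matrix(bg, size, size)
      # trace-like curve: one row per column, random smooth path
      if (stats::runif(1) < 0.85) {
        f <- stats::runif(1, 0.05, 0.3); ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 2, size / 3)
        rows <- round(size / 2 + amp * sin(f * xs + ph))
        rows <- clamp(rows, 1, size)
        x[cbind(rows, xs)] <- stats::runif(1, 0, 0.15)
      }
      y <- x
      if (stats::runif(1) > 0.1) {  # ~10% grid-free
        pitch <- stats::runif(1, 5, 9)
        phr <- stats::runif(1, 0, pitch); phc <- stats::runif(1, 0, pitch)
        a <- stats::runif(1, 0.15, 0.45)
        gr <- abs(((xs - phr) %% pitch)) < 1
        gc <- abs(((xs - phc) %% pitch)) < 1
        grid <- outer(gr, rep(FALSE, size), `|`) |
          outer(rep(FALSE, size), gc, `|`)
        y <- y - a * grid
      }
      clean[, , i] <- x
      noisy[, , i] <- clamp(y, 0, 1)
    }
    list(noisy = noisy, clean = clean)
  })
}
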
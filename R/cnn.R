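# Low-complexity temporal CNN for 20 Hz pulse detection.
#
# Three depth-wise separable 1-D convolutions run along time, with the 128
# mel bands as input features (no convolution along frequency: large
# frequency shifts are not expected in fin whale pulses). Each separable
# layer is a per-channel temporal kernel followed by a point-wise (1x1)
# channel-mixing convolution; the first two layers are followed by batch
# normalization, leaky ReLU and dropout. For training, global max pooling
# over time and a sigmoid turn the frame map into a segment-level pulse
# probability; for inference the pooling is dropped, yielding per-frame
# probabilities at frame rate (6.25 Hz with the default frontend). The mel
# input is compressed by log10(1 + x * 10^a) with a trainable exponent a.

#' CNN architecture configuration
#'
#' @param n_layers Number of depth-wise separable layers.
#' @param kernel Temporal kernel length.
#' @param channels Output channels per layer (last must be 1).
#' @param dropout Dropout probability after layers 1..(n_layers-1).
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @return A `fin_cnn_config` list.
#' @export
cnn_config <- function(n_layers = 3, kernel = 5, channels = c(128, 128, 1),
                       dropout = 0.25, leaky_slope = 0.01) {
  stopifnot(n_layers == length(channels), channels[n_layers] == 1,
            kernel %% 2 == 1)
  structure(list(n_layers = n_layers, kernel = kernel, channels = channels,
                 dropout = dropout, leaky_slope = leaky_slope),
            class = "fin_cnn_config")
}

#' Training configuration
#'
#' Defaults follow the published recipe: 50 epochs, batch 16, Adam with
#' learning rate 0.001 decaying 3% per epoch, L2 weight decay 0.04,
#' positives oversampled 4x, brown-noise augmentation at around -3 dB SNR
#' on 5 s windows.
#'
#' @param epochs,batch,lr,lr_decay,weight_decay Optimizer settings.
#' @param positive_oversampling Times each positive is presented per epoch.
#' @param augment_snr Mean augmentation SNR in dB.
#' @param augment_snr_jitter Half-width of the uniform SNR jitter (dB).
#' @param window Training segment length in seconds.
#' @param seed Integer seed covering init, shuffling, dropout and
#'   augmentation.
#' @return A `fin_train_config` list.
#' @export
train_config <- function(epochs = 50, batch = 16, lr = 0.001,
                         lr_decay = 0.03, weight_decay = 0.04,
                         positive_oversampling = 4, augment_snr = -3,
                         augment_snr_jitter = 1.5, window = 5, seed = 1L) {
  stopifnot(epochs >= 1, batch >= 1, lr > 0, lr_decay >= 0, lr_decay < 1,
            weight_decay >= 0, positive_oversampling >= 1)
  structure(list(epochs = epochs, batch = batch, lr = lr,
                 lr_decay = lr_decay, weight_decay = weight_decay,
                 positive_oversampling = as.integer(positive_oversampling),
                 augment_snr = augment_snr,
                 augment_snr_jitter = augment_snr_jitter,
                 window = window, seed = as.integer(seed)),
            class = "fin_train_config")
}

#' Build the detection model
#'
#' Instantiates the network with He-initialized weights. All trainable
#' scalars (depth-wise and point-wise convolution weights, point-wise
#' biases, batch-norm scale/shift, and the compression exponent) are held
#' in `model$params`.
#'
#' @param cfg A [cnn_config()].
#' @param frontend A [frontend_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `fin_cnn` model object.
#' @export
build_model <- function(cfg = cnn_config(), frontend = frontend_config(),
                        seed = 1L) {
  n_mels <- frontend$n_mels
  k <- cfg$kernel
  ch <- c(n_mels, cfg$channels)
  with_seed(seed, {
    params <- list(a = 0)
    buffers <- list()
    for (l in seq_len(cfg$n_layers)) {
      c_in <- ch[l]; c_out <- ch[l + 1]
      params[[paste0("dw", l)]] <-
        matrix(stats::rnorm(c_in * k, 0, sqrt(2 / k)), c_in, k)
      params[[paste0("pw", l)]] <-
        matrix(stats::rnorm(c_out * c_in, 0, sqrt(2 / c_in)), c_out, c_in)
      params[[paste0("b", l)]] <- rep(0, c_out)
      if (l < cfg$n_layers) {
        params[[paste0("gamma", l)]] <- rep(1, c_out)
        params[[paste0("beta", l)]] <- rep(0, c_out)
        buffers[[paste0("rmean", l)]] <- rep(0, c_out)
        buffers[[paste0("rvar", l)]] <- rep(1, c_out)
      }
    }
    structure(list(cfg = cfg, frontend = frontend, params = params,
                   buffers = buffers, history = NULL, trained = FALSE),
              class = "fin_cnn")
  })
}

#' Count trainable parameters
#'
#' @param model A `fin_cnn`.
#' @return Total number of trainable scalars, including the compression
#'   exponent.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "fin_cnn"))
  sum(vapply(model$params, length, 0L))
}

# ---- array helpers (X is [channels, T, batch]) ----

dwconv_forward <- function(X, dw) {
  d <- dim(X); Tn <- d[2]
  k <- ncol(dw); half <- k %/% 2
  Xp <- array(0, c(d[1], Tn + 2 * half, d[3]))
  Xp[, (half + 1):(half + Tn), ] <- X
  Y <- array(0, d)
  for (ki in seq_len(k)) {
    Y <- Y + Xp[, ki:(ki + Tn - 1), , drop = FALSE] * dw[, ki]
  }
  Y
}

dwconv_backward <- function(dY, X, dw) {
  d <- dim(X); Tn <- d[2]
  k <- ncol(dw); half <- k %/% 2
  Xp <- array(0, c(d[1], Tn + 2 * half, d[3]))
  Xp[, (half + 1):(half + Tn), ] <- X
  dYp <- array(0, c(d[1], Tn + 2 * half, d[3]))
  dYp[, (half + 1):(half + Tn), ] <- dY
  dX <- array(0, d)
  ddw <- matrix(0, nrow(dw), k)
  for (ki in seq_len(k)) {
    # correlation flips the kernel index for the input gradient
    dX <- dX + dYp[, (k - ki + 1):(k - ki + Tn), , drop = FALSE] * dw[, ki]
    ddw[, ki] <- rowSums(Xp[, ki:(ki + Tn - 1), , drop = FALSE] * dY,
                         dims = 1)
  }
  list(dX = dX, ddw = ddw)
}

pwconv_forward <- function(X, W, b) {
  d <- dim(X)
  Ym <- W %*% matrix(X, d[1], d[2] * d[3]) + b
  array(Ym, c(nrow(W), d[2], d[3]))
}

pwconv_backward <- function(dY, X, W) {
  d <- dim(X); dd <- dim(dY)
  dYm <- matrix(dY, dd[1], dd[2] * dd[3])
  Xm <- matrix(X, d[1], d[2] * d[3])
  list(dX = array(t(W) %*% dYm, d),
       dW = dYm %*% t(Xm),
       db = rowSums(dYm))
}

bn_eps <- 1e-5

bn_forward_train <- function(X, gamma, beta) {
  d <- dim(X); N <- d[2] * d[3]
  Xm <- matrix(X, d[1], N)
  mu <- rowMeans(Xm)
  v <- rowMeans((Xm - mu)^2)
  inv <- 1 / sqrt(v + bn_eps)
  xhat <- (Xm - mu) * inv
  Y <- array(xhat * gamma + beta, d)
  list(Y = Y, xhat = xhat, inv = inv, mu = mu, var = v)
}

bn_backward <- function(dY, cache, gamma) {
  d <- dim(dY); N <- d[2] * d[3]
  dYm <- matrix(dY, d[1], N)
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * gamma
  dX <- (cache$inv / N) *
    (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

bn_forward_eval <- function(X, gamma, beta, rmean, rvar) {
  d <- dim(X)
  Xm <- matrix(X, d[1], d[2] * d[3])
  xhat <- (Xm - rmean) / sqrt(rvar + bn_eps)
  array(xhat * gamma + beta, d)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass on a batch of raw mel-power arrays [n_mels, T, B].
# training=TRUE uses batch statistics and dropout and returns caches.
cnn_forward <- function(model, mel, training = FALSE) {
  p <- model$params; cfg <- model$cfg
  cache <- list(mel = mel)
  ln10 <- log(10)
  X <- log1p(mel * 10^p$a) / ln10
  cache$X0 <- X
  mom <- 0.1
  for (l in seq_len(cfg$n_layers)) {
    dwl <- p[[paste0("dw", l)]]
    Xc <- X
    cache[[paste0("in", l)]] <- Xc
    Y <- dwconv_forward(Xc, dwl)
    cache[[paste0("dwout", l)]] <- Y
    Y <- pwconv_forward(Y, p[[paste0("pw", l)]], p[[paste0("b", l)]])
    if (l < cfg$n_layers) {
      g <- p[[paste0("gamma", l)]]; be <- p[[paste0("beta", l)]]
      if (training) {
        bn <- bn_forward_train(Y, g, be)
        cache[[paste0("bn", l)]] <- bn
        cache[[paste0("bnin", l)]] <- Y
        model$buffers[[paste0("rmean", l)]] <-
          (1 - mom) * model$buffers[[paste0("rmean", l)]] + mom * bn$mu
        model$buffers[[paste0("rvar", l)]] <-
          (1 - mom) * model$buffers[[paste0("rvar", l)]] + mom * bn$var
        Y <- bn$Y
      } else {
        Y <- bn_forward_eval(Y, g, be,
                             model$buffers[[paste0("rmean", l)]],
                             model$buffers[[paste0("rvar", l)]])
      }
      neg <- Y < 0
      cache[[paste0("neg", l)]] <- neg
      Y[neg] <- Y[neg] * cfg$leaky_slope
      if (training && cfg$dropout > 0) {
        mask <- (array(stats::runif(length(Y)), dim(Y)) >= cfg$dropout) /
          (1 - cfg$dropout)
        cache[[paste0("mask", l)]] <- mask
        Y <- Y * mask
      }
    }
    X <- Y
  }
  list(frames = X, cache = cache, model = model)
}

# Backward pass from gradient on the frame map; returns gradients for every
# trainable parameter.
cnn_backward <- function(model, cache, dframes) {
  p <- model$params; cfg <- model$cfg
  grads <- list()
  dY <- dframes
  for (l in rev(seq_len(cfg$n_layers))) {
    if (l < cfg$n_layers) {
      mask <- cache[[paste0("mask", l)]]
      if (!is.null(mask)) dY <- dY * mask
      neg <- cache[[paste0("neg", l)]]
      dY[neg] <- dY[neg] * cfg$leaky_slope
      bnb <- bn_backward(dY, cache[[paste0("bn", l)]],
                         p[[paste0("gamma", l)]])
      grads[[paste0("gamma", l)]] <- bnb$dgamma
      grads[[paste0("beta", l)]] <- bnb$dbeta
      dY <- bnb$dX
    }
    pwb <- pwconv_backward(dY, cache[[paste0("dwout", l)]],
                           p[[paste0("pw", l)]])
    grads[[paste0("pw", l)]] <- pwb$dW
    grads[[paste0("b", l)]] <- pwb$db
    dwb <- dwconv_backward(pwb$dX, cache[[paste0("in", l)]],
                           p[[paste0("dw", l)]])
    grads[[paste0("dw", l)]] <- dwb$ddw
    dY <- dwb$dX
  }
  # through the compression: dX0/da = mel * 10^a / ((1 + mel*10^a))
  s <- cache$mel * 10^p$a
  grads$a <- sum(dY * (s / (1 + s)))
  grads
}

# Broadband SNR mixing used only for training augmentation (full-band
# powers over the whole segment).
mix_broadband <- function(signal, noise, snr_db) {
  p_sig <- mean(signal^2)
  p_noise <- mean(noise^2)
  signal + noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
}

#' Train the detection CNN
#'
#' Binary cross-entropy training on labelled audio segments. Each epoch,
#' positives are oversampled, segments are augmented with fresh brown noise
#' at around -3 dB SNR, converted to mel spectrograms, and batched through
#' Adam. Deterministic given `cfg$seed`.
#'
#' @param model A `fin_cnn` from [build_model()].
#' @param segments List of waveforms at the frontend target rate (equal
#'   lengths, typically 5 s).
#' @param labels Integer/logical vector: 1 = contains a pulse.
#' @param cfg A [train_config()].
#' @param augment Set `FALSE` to disable noise augmentation.
#' @param verbose Print per-epoch loss.
#' @return The trained model; `model$history$loss` holds mean epoch losses.
#' @export
train <- function(model, segments, labels, cfg = train_config(),
                  augment = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "fin_cnn"), length(segments) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes")
  }
  sr <- model$frontend$target_rate
  pos <- which(labels == 1); neg <- which(labels == 0)
  adam <- new.env(parent = emptyenv())
  adam$m <- lapply(model$params, function(x) x * 0)
  adam$v <- lapply(model$params, function(x) x * 0)
  adam$t <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  losses <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$lr * (1 - cfg$lr_decay)^(epoch - 1)
      idx <- sample(c(rep(pos, cfg$positive_oversampling), neg))
      batch_losses <- c()
      for (b0 in seq(1, length(idx), by = cfg$batch)) {
        bidx <- idx[b0:min(b0 + cfg$batch - 1, length(idx))]
        B <- length(bidx)
        mels <- vector("list", B)
        for (j in seq_len(B)) {
          seg <- segments[[bidx[j]]]
          if (augment) {
            snr <- stats::runif(1, cfg$augment_snr - cfg$augment_snr_jitter,
                                cfg$augment_snr + cfg$augment_snr_jitter)
            seg <- mix_broadband(seg, brown_noise(length(seg), sr), snr)
          }
          mels[[j]] <- mel_spectrogram(seg, model$frontend)$mel
        }
        Tn <- ncol(mels[[1]])
        X <- array(unlist(mels), c(model$frontend$n_mels, Tn, B))
        y <- labels[bidx]
        fw <- cnn_forward(model, X, training = TRUE)
        model <- fw$model
        fr <- fw$frames # [1, T, B]
        amax <- apply(fr[1, , , drop = FALSE], 3, which.max)
        z <- fr[cbind(1, amax, seq_len(B))]
        pb <- sigmoid(z)
        pb <- pmin(pmax(pb, 1e-12), 1 - 1e-12)
        loss <- -mean(y * log(pb) + (1 - y) * log(1 - pb))
        batch_losses <- c(batch_losses, loss)
        dz <- (pb - y) / B
        dframes <- array(0, dim(fr))
        dframes[cbind(1, amax, seq_len(B))] <- dz
        grads <- cnn_backward(model, fw$cache, dframes)
        adam$t <- adam$t + 1
        for (nm in names(model$params)) {
          g <- grads[[nm]] + cfg$weight_decay * model$params[[nm]]
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * g
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * g^2
          mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
          vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[epoch] <- mean(batch_losses)
      if (verbose) message(sprintf("epoch %d  loss %.4f", epoch,
                                   losses[epoch]))
    }
  })
  model$history <- list(loss = losses)
  model$trained <- TRUE
  model
}

#' Per-frame pulse probabilities
#'
#' Runs the trained network over a whole recording with the global max
#' pooling removed, yielding a pulse-presence probability for every
#' spectrogram frame (6.25 Hz with the default frontend).
#'
#' @param model A trained `fin_cnn`.
#' @param waveform Waveform at the frontend target rate (already
#'   preprocessed).
#' @return A `fin_frame_scores` list: `prob`, `time` (s), `frame_rate`.
#' @export
predict_frames <- function(model, waveform) {
  stopifnot(inherits(model, "fin_cnn"))
  ms <- mel_spectrogram(waveform, model$frontend)
  X <- array(ms$mel, c(dim(ms$mel), 1))
  fw <- cnn_forward(model, X, training = FALSE)
  structure(list(prob = sigmoid(fw$frames[1, , 1]),
                 time = ms$time, frame_rate = ms$frame_rate),
            class = "fin_frame_scores")
}

#' Pick pulse times from frame scores
#'
#' Retains the highest predictions above the threshold within sliding
#' windows: greedy non-maximum suppression so that no two detections are
#' closer than `min_separation` seconds. Times are frame centers.
#'
#' @param scores A `fin_frame_scores`.
#' @param threshold Detection probability threshold in (0, 1).
#' @param min_separation Minimum spacing between detections (s).
#' @return Data frame with `time` (s) and `score`, ordered by time.
#' @export
detect <- function(scores, threshold, min_separation = 4) {
  stopifnot(inherits(scores, "fin_frame_scores"),
            threshold > 0, threshold < 1)
  cand <- which(scores$prob > threshold)
  if (length(cand) == 0) {
    return(data.frame(time = numeric(), score = numeric()))
  }
  cand <- cand[order(scores$prob[cand], decreasing = TRUE)]
  keep_t <- numeric(); keep_s <- numeric()
  for (i in cand) {
    ti <- scores$time[i]
    if (all(abs(keep_t - ti) >= min_separation)) {
      keep_t <- c(keep_t, ti)
      keep_s <- c(keep_s, scores$prob[i])
    }
  }
  o <- order(keep_t)
  data.frame(time = keep_t[o], score = keep_s[o])
}

#' Save or load a detection model
#'
#' Model checkpoints are stored as RDS containers with the architecture and
#' frontend configuration embedded, so a loaded model is self-describing.
#'
#' @param model A `fin_cnn`.
#' @param path Checkpoint path.
#' @return `load_model` returns the `fin_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fin_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fin_cnn")) stop("not a detection model checkpoint")
  model
}
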
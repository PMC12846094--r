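# Image classifier: a pluggable convolutional backbone followed by the
# dense classification head (global average pooling, 256-unit dense,
# dropout 0.4, 128-unit dense, dropout 0.4, softmax output). The default
# backbone is a small 3-block CNN trained from scratch (feature width
# 64), sized so the whole pipeline trains on one CPU; the named
# ImageNet-scale backbones are recognized but error unless their weights
# are available locally, which this build does not ship.
#
# All tensor math is plain R: convolutions are evaluated as nine shifted
# slice multiplications (3x3 kernels), which maps onto BLAS matrix
# products and needs no compiled code.

#' Classification head specification
#'
#' @param dense1_units,dense2_units widths of the two dense layers.
#' @param dropout1,dropout2 dropout rates after each dense layer.
#' @param output_units number of classes (2 or 3).
#' @return an object of class `semg_head_spec`.
#' @export
head_spec <- function(dense1_units = 256L, dropout1 = 0.4,
                      dense2_units = 128L, dropout2 = 0.4,
                      output_units = 2L) {
  check_that(dense1_units > 0 && dense2_units > 0, "units must be positive")
  check_that(dropout1 >= 0 && dropout1 < 1 && dropout2 >= 0 && dropout2 < 1,
             "dropout rates must be in [0, 1)")
  check_that(output_units %in% c(2L, 3L), "output_units must be 2 or 3")
  structure(list(pooling = "global_average",
                 dense1_units = as.integer(dense1_units),
                 dropout1 = dropout1,
                 dense2_units = as.integer(dense2_units),
                 dropout2 = dropout2,
                 output_units = as.integer(output_units),
                 output_activation = "softmax"),
            class = "semg_head_spec")
}

#' Training specification for the image classifier
#'
#' Defaults follow the published training recipe: Adam, learning rate
#' 0.002, batch size 128, 70 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs (no early stopping).
#' @param seed controls weight initialization, shuffling and dropout masks.
#' @param backbone_id `"scratch_small_cnn"` or one of the recognized
#'   pre-trained identifiers (`"inception_resnet_v2"`, `"densenet121"`,
#'   `"resnet50"`, `"inception_v3"`), which require locally available
#'   weights.
#' @param fine_tune_all train all backbone layers (always true for the
#'   scratch backbone).
#' @param validation_fraction fraction of training windows held out
#'   (stratified) for the per-epoch validation curves.
#' @param conv_widths filter counts of the three scratch-backbone blocks;
#'   the last is the feature width fed to the head (64 by default).
#' @return an object of class `semg_train_spec`.
#' @export
train_spec <- function(learning_rate = 0.002, batch_size = 128L,
                       epochs = 70L, seed = 1L,
                       backbone_id = "scratch_small_cnn",
                       fine_tune_all = TRUE,
                       validation_fraction = 0.1,
                       conv_widths = c(16L, 32L, 64L)) {
  check_that(learning_rate > 0, "learning_rate must be positive")
  check_that(epochs >= 1, "epochs must be >= 1")
  known <- c("scratch_small_cnn", "inception_resnet_v2", "densenet121",
             "resnet50", "inception_v3")
  check_that(backbone_id %in% known,
             paste("unknown backbone:", backbone_id))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = "adam", epochs = as.integer(epochs),
                 seed = as.integer(seed), backbone_id = backbone_id,
                 fine_tune_all = isTRUE(fine_tune_all),
                 validation_fraction = validation_fraction,
                 conv_widths = as.integer(conv_widths)),
            class = "semg_train_spec")
}

#' Describe the dense classification head
#'
#' @param num_classes 2 or 3.
#' @param head a [head_spec()].
#' @param feature_width backbone output width F fed to the head.
#' @return list with the ordered `layers` description and `n_params`, the
#'   closed-form parameter count
#'   `F*256 + 256 + 256*128 + 128 + 128*C + C`.
#' @export
build_head <- function(num_classes, head = head_spec(output_units = num_classes),
                       feature_width = 64L) {
  check_that(num_classes %in% c(2L, 3L), "num_classes must be 2 or 3")
  d1 <- head$dense1_units
  d2 <- head$dense2_units
  layers <- list(
    list(type = "global_average_pooling", out = feature_width),
    list(type = "dense", units = d1, activation = "relu"),
    list(type = "dropout", rate = head$dropout1),
    list(type = "dense", units = d2, activation = "relu"),
    list(type = "dropout", rate = head$dropout2),
    list(type = "dense", units = num_classes, activation = "softmax"))
  n_params <- feature_width * d1 + d1 + d1 * d2 + d2 + d2 * num_classes +
    num_classes
  list(layers = layers, n_params = n_params, feature_width = feature_width)
}

# -- tensor primitives -------------------------------------------------------
# Internal activations use an H x W x N x C layout: flattening an
# (H, W, N, C) slice column-wise yields exactly the (pixel*image) x
# channel matrix the convolution products need, so no aperm is required
# anywhere in the hot path.

conv3x3_forward <- function(x, w, b) {
  d <- dim(x)
  h <- d[1]; wd <- d[2]; n <- d[3]; cin <- d[4]
  cout <- length(b)
  xp <- array(0, c(h + 2, wd + 2, n, cin))
  xp[2:(h + 1), 2:(wd + 1), , ] <- x
  y <- matrix(rep(b, each = h * wd * n), h * wd * n, cout)
  o <- 0
  for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1
    sl <- xp[(1 + dy):(h + dy), (1 + dx):(wd + dx), , , drop = FALSE]
    y <- y + matrix(sl, ncol = cin) %*%
      w[((o - 1) * cin + 1):(o * cin), , drop = FALSE]
  }
  array(y, c(h, wd, n, cout))
}

conv3x3_backward <- function(x, w, dy_arr) {
  d <- dim(x)
  h <- d[1]; wd <- d[2]; n <- d[3]; cin <- d[4]
  cout <- ncol(w)
  xp <- array(0, c(h + 2, wd + 2, n, cin))
  xp[2:(h + 1), 2:(wd + 1), , ] <- x
  dym <- matrix(dy_arr, ncol = cout)
  dw <- matrix(0, nrow(w), cout)
  dxp <- array(0, c(h + 2, wd + 2, n, cin))
  o <- 0
  for (dy in 0:2) for (dx in 0:2) {
    o <- o + 1
    rows <- ((o - 1) * cin + 1):(o * cin)
    sl <- xp[(1 + dy):(h + dy), (1 + dx):(wd + dx), , , drop = FALSE]
    dw[rows, ] <- crossprod(matrix(sl, ncol = cin), dym)
    dxo <- dym %*% t(w[rows, , drop = FALSE])
    dxp[(1 + dy):(h + dy), (1 + dx):(wd + dx), , ] <-
      dxp[(1 + dy):(h + dy), (1 + dx):(wd + dx), , ] +
      array(dxo, c(h, wd, n, cin))
  }
  list(dx = dxp[2:(h + 1), 2:(wd + 1), , , drop = FALSE],
       dw = dw, db = colSums(dym))
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2
  w2 <- d[2] %/% 2
  i1 <- seq(1, 2 * h2, by = 2)
  j1 <- seq(1, 2 * w2, by = 2)
  cand <- list(x[i1, j1, , , drop = FALSE], x[i1 + 1, j1, , , drop = FALSE],
               x[i1, j1 + 1, , , drop = FALSE],
               x[i1 + 1, j1 + 1, , , drop = FALSE])
  y <- cand[[1]]
  which_m <- array(1L, dim(y))
  for (k in 2:4) {
    upd <- cand[[k]] > y
    y[upd] <- cand[[k]][upd]
    which_m[upd] <- k
  }
  list(y = y, which = which_m)
}

maxpool2_backward <- function(x_dim, pool, dy_arr) {
  dx <- array(0, x_dim)
  h2 <- dim(dy_arr)[1]
  w2 <- dim(dy_arr)[2]
  i1 <- seq(1, 2 * h2, by = 2)
  j1 <- seq(1, 2 * w2, by = 2)
  for (k in 1:4) {
    sel <- pool$which == k
    if (!any(sel)) next
    di <- (k - 1) %% 2
    dj <- (k - 1) %/% 2
    sub <- dx[i1 + di, j1 + dj, , , drop = FALSE]
    sub[sel] <- sub[sel] + dy_arr[sel]
    dx[i1 + di, j1 + dj, , ] <- sub
  }
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])
  matrix(colMeans(m), d[3], d[4])        # N x C
}

gap_backward <- function(x_dim, dy_mat) {
  scale <- 1 / (x_dim[1] * x_dim[2])
  array(rep(as.numeric(dy_mat * scale), each = x_dim[1] * x_dim[2]), x_dim)
}

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
}

init_scratch_params <- function(num_classes, head,
                                widths = c(16L, 32L, 64L)) {
  # input channels: 3 image planes + 1 row-coordinate plane (the scale
  # axis), so the network can pool position-aware spectral features
  list(
    wc1 = he_init(9 * 4, widths[1]), bc1 = numeric(widths[1]),
    wc2 = he_init(9 * widths[1], widths[2]), bc2 = numeric(widths[2]),
    wc3 = he_init(9 * widths[2], widths[3]), bc3 = numeric(widths[3]),
    wd1 = he_init(widths[3], head$dense1_units),
    bd1 = numeric(head$dense1_units),
    wd2 = he_init(head$dense1_units, head$dense2_units),
    bd2 = numeric(head$dense2_units),
    wo = he_init(head$dense2_units, num_classes),
    bo = numeric(num_classes))
}

# append a normalized row-coordinate plane: scalogram rows are scales,
# and the vertical position of spectral energy is the fatigue cue that
# global average pooling would otherwise discard
add_coord_channel <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], d[3], d[4] + 1))
  out[, , , seq_len(d[4])] <- x
  out[, , , d[4] + 1] <- (seq_len(d[1]) - 1) / (d[1] - 1)
  out
}

scratch_forward <- function(x, par, head, training = FALSE) {
  x <- add_coord_channel(x)
  cache <- list(x = x)
  a1 <- conv3x3_forward(x, par$wc1, par$bc1)
  r1 <- pmax(a1, 0); p1 <- maxpool2_forward(r1)
  a2 <- conv3x3_forward(p1$y, par$wc2, par$bc2)
  r2 <- pmax(a2, 0); p2 <- maxpool2_forward(r2)
  a3 <- conv3x3_forward(p2$y, par$wc3, par$bc3)
  r3 <- pmax(a3, 0); p3 <- maxpool2_forward(r3)
  feat <- gap_forward(p3$y)
  h1 <- pmax(sweep(feat %*% par$wd1, 2, par$bd1, "+"), 0)
  m1 <- NULL
  if (training && head$dropout1 > 0) {
    m1 <- matrix(stats::runif(length(h1)) >= head$dropout1, nrow(h1)) /
      (1 - head$dropout1)
    h1 <- h1 * m1
  }
  h2 <- pmax(sweep(h1 %*% par$wd2, 2, par$bd2, "+"), 0)
  m2 <- NULL
  if (training && head$dropout2 > 0) {
    m2 <- matrix(stats::runif(length(h2)) >= head$dropout2, nrow(h2)) /
      (1 - head$dropout2)
    h2 <- h2 * m2
  }
  logits <- sweep(h2 %*% par$wo, 2, par$bo, "+")
  e <- exp(logits - apply(logits, 1, max))
  prob <- e / rowSums(e)
  list(prob = prob, cache = list(a1 = a1, r1 = r1, p1 = p1, a2 = a2,
                                 r2 = r2, p2 = p2, a3 = a3, r3 = r3,
                                 p3 = p3, feat = feat, h1 = h1, m1 = m1,
                                 h2 = h2, m2 = m2, x = x))
}

scratch_backward <- function(par, head, fw, y_onehot) {
  ca <- fw$cache
  n <- nrow(y_onehot)
  dlogits <- (fw$prob - y_onehot) / n
  grads <- list()
  grads$wo <- crossprod(ca$h2, dlogits)
  grads$bo <- colSums(dlogits)
  dh2 <- dlogits %*% t(par$wo)
  if (!is.null(ca$m2)) dh2 <- dh2 * ca$m2
  dh2 <- dh2 * (ca$h2 > 0)
  grads$wd2 <- crossprod(ca$h1, dh2)
  grads$bd2 <- colSums(dh2)
  dh1 <- dh2 %*% t(par$wd2)
  if (!is.null(ca$m1)) dh1 <- dh1 * ca$m1
  dh1 <- dh1 * (ca$h1 > 0)
  grads$wd1 <- crossprod(ca$feat, dh1)
  grads$bd1 <- colSums(dh1)
  dfeat <- dh1 %*% t(par$wd1)
  dp3 <- gap_backward(dim(ca$p3$y), dfeat)
  dr3 <- maxpool2_backward(dim(ca$r3), ca$p3, dp3) * (ca$a3 > 0)
  bk3 <- conv3x3_backward(ca$p2$y, par$wc3, dr3)
  grads$wc3 <- bk3$dw; grads$bc3 <- bk3$db
  dr2 <- maxpool2_backward(dim(ca$r2), ca$p2, bk3$dx) * (ca$a2 > 0)
  bk2 <- conv3x3_backward(ca$p1$y, par$wc2, dr2)
  grads$wc2 <- bk2$dw; grads$bc2 <- bk2$db
  dr1 <- maxpool2_backward(dim(ca$r1), ca$p1, bk2$dx) * (ca$a1 > 0)
  bk1 <- conv3x3_backward(ca$x, par$wc1, dr1)
  grads$wc1 <- bk1$dw; grads$bc1 <- bk1$db
  grads
}

#' Stack scalogram images into a training tensor
#'
#' @param images list of `semg_scalogram_image`.
#' @return numeric array `H x W x 3 x N` with intensities scaled to
#'   `[0, 1]`.
#' @export
image_stack <- function(images) {
  check_that(length(images) >= 1, "no images")
  d <- dim(images[[1]]$pixels)
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) {
    check_that(all(dim(images[[i]]$pixels) == d), "inconsistent image sizes")
    out[, , , i] <- images[[i]]$pixels / 255
  }
  out
}

#' Train the image classifier
#'
#' Trains the scratch backbone plus dense head with Adam on softmax
#' cross-entropy, recording per-epoch training and validation loss and
#' accuracy curves. Runs are reproducible for a fixed seed.
#'
#' @param images array `H x W x 3 x N` in `[0, 1]` (see [image_stack()])
#'   with H and W divisible by 8, or a list of `semg_scalogram_image`.
#' @param y labels (factor or character), at least 2 classes.
#' @param spec a [train_spec()].
#' @param head a [head_spec()]; `output_units` is set from the data.
#' @return a `semg_cnn_model` with fields `params`, `classes`, `history`
#'   (data.frame epoch, loss, acc, val_loss, val_acc) and `head`.
#' @export
train_image_model <- function(images, y, spec = train_spec(),
                              head = head_spec()) {
  if (is.list(images) && !is.array(images)) images <- image_stack(images)
  if (spec$backbone_id != "scratch_small_cnn") {
    stop(structure(class = c("semg_backbone_unavailable", "error",
                             "condition"),
                   list(message = paste0(
                     "pre-trained backbone '", spec$backbone_id,
                     "' has no locally available weights; use the ",
                     "scratch_small_cnn backbone"), call = NULL)))
  }
  if (!is.factor(y)) y <- factor(y)
  classes <- levels(droplevels(y))
  y <- droplevels(y)
  check_that(length(classes) >= 2, "single-class dataset")
  n <- dim(images)[4]
  check_that(n == length(y), "images and labels differ in length")
  check_that(dim(images)[1] %% 8 == 0 && dim(images)[2] %% 8 == 0,
             "image side must be divisible by 8 for the 3 pooling stages")
  nc <- length(classes)
  head$output_units <- nc
  yi <- as.integer(y)
  images <- aperm(images, c(1, 2, 4, 3))   # internal H x W x N x C layout
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  par <- init_scratch_params(nc, head, spec$conv_widths)

  # stratified validation split
  val_idx <- integer(0)
  if (spec$validation_fraction > 0 && n >= 20) {
    for (cl in seq_len(nc)) {
      ii <- which(yi == cl)
      nv <- max(1, floor(length(ii) * spec$validation_fraction))
      val_idx <- c(val_idx, sample(ii, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  adam_m <- lapply(par, function(p) p * 0)
  adam_v <- lapply(par, function(p) p * 0)
  step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  onehot <- function(idx) {
    m <- matrix(0, length(idx), nc)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  history <- data.frame()
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_correct <- 0
    for (s0 in seq(1, length(ord), by = spec$batch_size)) {
      bidx <- ord[s0:min(s0 + spec$batch_size - 1, length(ord))]
      xb <- images[, , bidx, , drop = FALSE]
      fw <- scratch_forward(xb, par, head, training = TRUE)
      yb <- onehot(yi[bidx])
      pr <- pmax(fw$prob, 1e-12)
      ep_loss <- ep_loss - sum(log(pr[yb == 1]))
      ep_correct <- ep_correct + sum(max.col(fw$prob, "first") == yi[bidx])
      grads <- scratch_backward(par, head, fw, yb)
      step <- step + 1
      for (nm in names(par)) {
        g <- grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - spec$learning_rate * mhat /
          (sqrt(vhat) + eps)
      }
    }
    row <- data.frame(epoch = ep, loss = ep_loss / length(ord),
                      acc = ep_correct / length(ord),
                      val_loss = NA_real_, val_acc = NA_real_)
    if (length(val_idx)) {
      fv <- scratch_forward(images[, , val_idx, , drop = FALSE], par, head)
      pv <- pmax(fv$prob, 1e-12)
      row$val_loss <- -mean(log(pv[cbind(seq_along(val_idx),
                                         yi[val_idx])]))
      row$val_acc <- mean(max.col(fv$prob, "first") == yi[val_idx])
    }
    history <- rbind(history, row)
  }
  structure(list(params = par, classes = classes, head = head, spec = spec,
                 history = history,
                 head_description = build_head(nc, head,
                                               spec$conv_widths[3])),
            class = "semg_cnn_model")
}

#' Predict with a trained image classifier
#'
#' Dropout is inactive at inference, so repeated passes on identical
#' input are identical. Ties break toward the lower-ordered class.
#'
#' @param object a `semg_cnn_model`.
#' @param newdata image array `H x W x 3 x N` or list of images.
#' @param ... unused.
#' @return list with `prob` and `class` as in [predict.semg_model()].
#' @export
predict.semg_cnn_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.array(newdata)) newdata <- image_stack(newdata)
  n <- dim(newdata)[4]
  newdata <- aperm(newdata, c(1, 2, 4, 3))
  prob <- matrix(0, n, length(object$classes))
  # bounded-memory batches
  for (s0 in seq(1, n, by = 256)) {
    ii <- s0:min(s0 + 255, n)
    fw <- scratch_forward(newdata[, , ii, , drop = FALSE], object$params,
                          object$head)
    prob[ii, ] <- fw$prob
  }
  colnames(prob) <- object$classes
  lab <- factor(object$classes[max.col(prob, ties.method = "first")],
                levels = object$classes, ordered = TRUE)
  list(prob = prob, class = lab)
}
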
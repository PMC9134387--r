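#' Image classifier configuration
#'
#' Configuration for the binary snapshot classifier. The default
#' architecture is a compact multilayer perceptron on downscaled RGB
#' pixels (`compact_mlp`: one hidden ReLU layer, sigmoid output) trained
#' with the Adam optimizer on binary cross-entropy. The method contract —
#' one probability per image, aggregated per compound by the median, with
#' the checkpoint of lowest validation loss retained — is architecture-
#' agnostic, so a small network suffices on CPU.
#'
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam step size (> 0); the default suits the small
#'   network and per-image cross-entropy at the default downscale.
#' @param batch_size minibatch size.
#' @param image_edge_px training-time square downscale edge; images are
#'   block-averaged (or subsampled) to this size before training. The
#'   coarse default acts as an aggressive pooling stage: it trades ring-
#'   level detail for translation robustness, which empirically helps the
#'   per-compound median.
#' @param seed integer seed controlling weight initialization and
#'   minibatch order.
#' @param architecture `"compact_mlp"` or `"logistic"` (no hidden layer).
#' @param hidden_units hidden-layer width for `compact_mlp`.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(epochs = 10L, learning_rate = 3e-3,
                              batch_size = 64L, image_edge_px = 16L,
                              seed = 1L,
                              architecture = c("compact_mlp", "logistic"),
                              hidden_units = 32L) {
  architecture <- match.arg(architecture)
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L,
            image_edge_px >= 4L, hidden_units >= 1L)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 image_edge_px = as.integer(image_edge_px),
                 seed = as.integer(seed), architecture = architecture,
                 hidden_units = as.integer(hidden_units)),
            class = "classifier_config")
}

#' Load snapshot images as a flat feature matrix
#'
#' Reads each manifest image, downscales it to `edge_px` (block average
#' when the source edge is divisible, nearest-neighbour subsampling
#' otherwise) and flattens RGB planes into one row per image.
#'
#' @param manifest a `snapshot_manifest` (rows define image order).
#' @param edge_px target square edge.
#' @return numeric matrix `n_images x (edge_px^2 * 3)`; attribute
#'   `compound_id` aligns rows with compounds.
#' @export
load_image_features <- function(manifest, edge_px) {
  n <- nrow(manifest)
  x <- matrix(0, n, edge_px * edge_px * 3L)
  for (i in seq_len(n)) {
    if (!file.exists(manifest$path[i]))
      stop(sprintf("missing image for compound %s at angle (%g,%g,%g): %s",
                   manifest$compound_id[i], manifest$angle_x[i],
                   manifest$angle_y[i], manifest$angle_z[i], manifest$path[i]))
    img <- png::readPNG(manifest$path[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    x[i, ] <- as.vector(downscale_image(img[, , 1:3, drop = FALSE], edge_px))
  }
  attr(x, "compound_id") <- manifest$compound_id
  x
}

downscale_image <- function(img, edge) {
  px <- dim(img)[1L]
  if (px == edge) return(img)
  if (px %% edge == 0L) {
    f <- px %/% edge
    g <- rep(seq_len(edge), each = f)
    out <- array(0, c(edge, edge, 3L))
    for (ch in 1:3)
      out[, , ch] <- t(rowsum(t(rowsum(img[, , ch], g)), g)) / (f * f)
    out
  } else {
    idx <- ceiling(seq_len(edge) * px / edge)
    img[idx, idx, , drop = FALSE]
  }
}

# ---- compact MLP ------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

mlp_init <- function(d, h, architecture) {
  if (architecture == "logistic")
    list(W2 = matrix(stats::rnorm(d, 0, sqrt(1 / d)), d, 1L), b2 = 0)
  else
    list(W1 = matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h),
         b1 = rep(0, h),
         W2 = matrix(stats::rnorm(h, 0, sqrt(1 / h)), h, 1L), b2 = 0)
}

mlp_forward <- function(w, x) {
  if (is.null(w$W1)) return(as.vector(sigmoid(x %*% w$W2 + w$b2)))
  a1 <- pmax(x %*% w$W1 + rep(w$b1, each = nrow(x)), 0)
  as.vector(sigmoid(a1 %*% w$W2 + w$b2))
}

mlp_gradient <- function(w, x, y) {
  n <- nrow(x)
  if (is.null(w$W1)) {
    p <- sigmoid(x %*% w$W2 + w$b2)
    dz <- (p - y) / n
    return(list(W2 = crossprod(x, dz), b2 = sum(dz)))
  }
  z1 <- x %*% w$W1 + rep(w$b1, each = n)
  a1 <- pmax(z1, 0)
  p <- sigmoid(a1 %*% w$W2 + w$b2)
  dz2 <- (p - y) / n
  dz1 <- (dz2 %*% t(w$W2)) * (z1 > 0)
  list(W1 = crossprod(x, dz1), b1 = colSums(dz1),
       W2 = crossprod(a1, dz2), b2 = sum(dz2))
}

adam_step <- function(state, w, g, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, w = w)
}

#' Train the binary snapshot classifier
#'
#' Trains the configured network on per-image binary cross-entropy, where
#' every snapshot of a compound inherits that compound's class label.
#' After each epoch the validation loss is recorded; the returned model
#' carries the weights of the epoch with the lowest validation loss
#' (earliest epoch on ties), selected exactly as [select_checkpoint()]
#' does. Training is a pure function of (data, config).
#'
#' @param manifests `snapshot_manifest` for the training compounds.
#' @param labels named binary vector (by compound_id) covering every
#'   training compound; must contain both classes.
#' @param val_manifests,val_labels validation counterpart; compound sets
#'   must be disjoint from training.
#' @param config a [classifier_config()].
#' @return a `snapshot_classifier`: list with `weights` (best checkpoint),
#'   `best_epoch`, `loss_record` (epoch, train_loss, val_loss), `config`.
#' @export
train_classifier <- function(manifests, labels, val_manifests, val_labels,
                             config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  tr_ids <- unique(manifests$compound_id)
  va_ids <- unique(val_manifests$compound_id)
  if (length(intersect(tr_ids, va_ids)))
    stop("training and validation compound sets overlap")
  if (!all(tr_ids %in% names(labels)) || !all(va_ids %in% names(val_labels)))
    stop("every compound in the manifests needs a label")
  y <- as.numeric(labels[manifests$compound_id])
  yv <- as.numeric(val_labels[val_manifests$compound_id])
  if (length(unique(y)) < 2L)
    stop("training labels are single-class; classifier undefined")

  x <- load_image_features(manifests, config$image_edge_px)
  xv <- load_image_features(val_manifests, config$image_edge_px)
  d <- ncol(x)
  n <- nrow(x)

  sq_with_seed(config$seed, {
    w <- mlp_init(d, config$hidden_units, config$architecture)
    st <- list(m = lapply(w, function(p) p * 0), v = lapply(w, function(p) p * 0))
    t_step <- 0L
    losses <- data.frame(epoch = integer(), train_loss = numeric(),
                         val_loss = numeric())
    best <- list(loss = Inf, w = w, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (b in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1L, n)]
        g <- mlp_gradient(w, x[idx, , drop = FALSE], y[idx])
        t_step <- t_step + 1L
        upd <- adam_step(st, w, g, config$learning_rate, t_step)
        st <- upd$state; w <- upd$w
      }
      tl <- bce_loss(mlp_forward(w, x), y)
      vl <- bce_loss(mlp_forward(w, xv), yv)
      losses <- rbind(losses, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, w = w, epoch = ep)
      sq_log("classifier", "epoch %d/%d train_loss=%.4f val_loss=%.4f",
             ep, config$epochs, tl, vl)
    }
  })
  structure(list(weights = best$w, best_epoch = best$epoch,
                 loss_record = losses, config = config),
            class = "snapshot_classifier")
}

#' Select the checkpoint epoch from a validation-loss record
#'
#' The retained checkpoint is the epoch with minimal validation loss;
#' ties resolve to the earliest epoch.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @return integer epoch index.
#' @export
select_checkpoint <- function(val_losses) {
  stopifnot(length(val_losses) >= 1L)
  which.min(val_losses)
}

#' @export
print.snapshot_classifier <- function(x, ...) {
  cat(sprintf("<snapshot_classifier %s> best epoch %d/%d (val_loss=%.4f)\n",
              x$config$architecture, x$best_epoch, nrow(x$loss_record),
              min(x$loss_record$val_loss)))
  invisible(x)
}

#' Per-image probabilities and per-compound medians
#'
#' Applies the trained classifier to every manifest image and aggregates
#' per compound by the arithmetic median of its per-image probabilities
#' (invariant to any permutation of a compound's images).
#'
#' @param model a `snapshot_classifier`.
#' @param manifests a `snapshot_manifest` (rendered with the training
#'   render parameters).
#' @return a `probability_table` data.frame (`compound_id`, `n_images`,
#'   `median_probability`), with attribute `per_image` holding the
#'   manifest plus a `probability` column in manifest order.
#' @export
predict_probabilities <- function(model, manifests) {
  stopifnot(inherits(model, "snapshot_classifier"))
  x <- load_image_features(manifests, model$config$image_edge_px)
  p <- mlp_forward(model$weights, x)
  per_image <- cbind(as.data.frame(manifests), probability = p)
  ids <- unique(manifests$compound_id)
  med <- vapply(ids, function(id) stats::median(p[manifests$compound_id == id]), 0)
  ni <- vapply(ids, function(id) sum(manifests$compound_id == id), 0L)
  structure(data.frame(compound_id = ids, n_images = ni,
                       median_probability = unname(med),
                       stringsAsFactors = FALSE),
            per_image = per_image,
            class = c("probability_table", "data.frame"))
}

#' Write a probability table (and optional per-image long format) as CSV
#'
#' @param table a `probability_table`.
#' @param path CSV path; with `per_image = TRUE` the long-format table
#'   goes to `<path>.images.csv`.
#' @param per_image also write the per-image probabilities.
#' @export
write_probability_table <- function(table, path, per_image = FALSE) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  if (per_image)
    utils::write.csv(attr(table, "per_image"), paste0(path, ".images.csv"),
                     row.names = FALSE)
  invisible(path)
}
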
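# Experience guidance network: a one-hidden-layer value regressor over
# (molecule, template) pair fingerprints. Input 4096 (molecule half ||
# template half), hidden 256 rectified units, scalar output squashed by the
# logistic into (0, 1). Trained by minimizing squared error against the
# q_bar labels harvested from finished search trees, with Adam and dropout
# 0.1 on the hidden layer. Labels live on the reward scale (roughly [-z, z]
# once +/-z rewards enter the averages) and are mapped affinely into [0, 1]
# at training time; predictions are used directly as Q0 in (0, 1), which
# keeps initial scores small relative to the success reward.

.EGN_EPS <- 1e-7

#' Initialize experience-guidance-network parameters
#'
#' Random weights (scaled normal initialization), zero biases.
#'
#' @param input_dim Input dimension (molecule half + template half).
#' @param hidden_dim Hidden-layer width.
#' @param dropout_rate Dropout probability on the hidden layer during
#'   training.
#' @param seed Integer seed for the weight draw.
#' @return List of class `egn_params` with `W1`, `b1`, `W2`, `b2`,
#'   `dropout_rate`, `init_seed`.
#' @export
egn_init <- function(input_dim = 4096L, hidden_dim = 256L,
                     dropout_rate = 0.1, seed = 0L) {
  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(input_dim * hidden_dim, sd = sqrt(2 / input_dim)),
                 input_dim, hidden_dim)
    W2 <- matrix(stats::rnorm(hidden_dim, sd = 1 / sqrt(hidden_dim)),
                 hidden_dim, 1L)
  })
  structure(
    list(W1 = W1, b1 = numeric(hidden_dim), W2 = W2, b2 = 0,
         dropout_rate = dropout_rate, init_seed = as.integer(seed),
         input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim)),
    class = "egn_params"
  )
}

#' @export
print.egn_params <- function(x, ...) {
  cat(sprintf("<egn_params> %d -> %d -> 1, dropout %.2f, init seed %d\n",
              x$input_dim, x$hidden_dim, x$dropout_rate, x$init_seed))
  invisible(x)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.egn_forward <- function(params, X) {
  Z1 <- sweep(as.matrix(X %*% params$W1), 2L, params$b1, "+")
  H <- pmax(Z1, 0)
  p <- .sigmoid(as.numeric(H %*% params$W2) + params$b2)
  pmin(pmax(p, .EGN_EPS), 1 - .EGN_EPS)
}

#' Predict the value of feature vectors
#'
#' Deterministic feed-forward pass (dropout inactive); output strictly in
#' (0, 1).
#'
#' @param params `egn_params`.
#' @param features Numeric vector of length `input_dim`, or a (possibly
#'   sparse) matrix with `input_dim` columns, one row per pair.
#' @return Numeric vector of predictions in (0, 1).
#' @export
egn_predict <- function(params, features) {
  stopifnot(inherits(params, "egn_params"))
  if (is.null(dim(features))) {
    if (length(features) != params$input_dim) {
      stop_egmcts("argument", sprintf(
        "feature length %d does not match input dimension %d",
        length(features), params$input_dim))
    }
    features <- matrix(features, 1L)
  } else if (ncol(features) != params$input_dim) {
    stop_egmcts("argument", sprintf(
      "feature width %d does not match input dimension %d",
      ncol(features), params$input_dim))
  }
  .egn_forward(params, features)
}

#' Predict values for (molecule, template) id pairs
#'
#' Featurizes each pair with [featurize_pair()] and runs one batched
#' forward pass.
#'
#' @param params `egn_params`.
#' @param molecule_ids,template_ids Equal-length character vectors.
#' @return Numeric vector of predictions in (0, 1).
#' @export
egn_predict_pairs <- function(params, molecule_ids, template_ids) {
  nbits <- params$input_dim %/% 2L
  n <- length(molecule_ids)
  # direct row-gather: x %*% W1 for a 0/1 vector is a sum of W1 rows
  Z1 <- matrix(0, n, params$hidden_dim)
  for (i in seq_len(n)) {
    idx <- featurize_pair(molecule_ids[i], template_ids[i], nbits) + 1L
    Z1[i, ] <- colSums(params$W1[idx, , drop = FALSE])
  }
  Z1 <- sweep(Z1, 2L, params$b1, "+")
  H <- pmax(Z1, 0)
  p <- .sigmoid(as.numeric(H %*% params$W2) + params$b2)
  pmin(pmax(p, .EGN_EPS), 1 - .EGN_EPS)
}

#' Map a search-scale score into the network's label range
#'
#' Scores collected from search live on the reward scale, roughly
#' \eqn{[-z, z]}; the network regresses targets in \eqn{[0, 1]}. The map is
#' affine with clipping: `(q + z) / (2 z)` clipped to \eqn{[0, 1]}.
#'
#' @param q Numeric scores.
#' @param z Reward magnitude used during search.
#' @return Labels in \eqn{[0, 1]}.
#' @export
squash_label <- function(q, z = 10) {
  pmin(pmax((q + z) / (2 * z), 0), 1)
}

#' Train the network on labelled pair features
#'
#' Minimizes mean squared error with Adam (learning rate `lr`, moment
#' decays 0.9/0.999), mini-batches of `batch_size`, and inverted dropout at
#' rate `params$dropout_rate` on the hidden layer. Deterministic given
#' `seed`. `epochs = 0` returns the parameters unchanged.
#'
#' @param params `egn_params` to start from.
#' @param features Matrix (dense or sparse) with one row per example and
#'   `input_dim` columns.
#' @param labels Numeric vector of targets in \eqn{[0, 1]}.
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed for shuffling and dropout.
#' @return New `egn_params`.
#' @export
egn_train <- function(params, features, labels, epochs = 20L,
                      batch_size = 128L, lr = 1e-3, seed = 0L) {
  stopifnot(inherits(params, "egn_params"))
  n <- nrow(features)
  if (is.null(n) || n == 0L || length(labels) == 0L) {
    stop_egmcts("argument", "training requires a non-empty dataset")
  }
  if (length(labels) != n) {
    stop_egmcts("argument", "features and labels disagree in length")
  }
  if (ncol(features) != params$input_dim) {
    stop_egmcts("argument", "feature width does not match input dimension")
  }
  if (epochs == 0L) return(params)
  drop_p <- params$dropout_rate
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  W1 <- params$W1; b1 <- params$b1; W2 <- params$W2; b2 <- params$b2
  mom <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
  vel <- mom
  t <- 0L
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        X <- features[idx, , drop = FALSE]
        y <- labels[idx]
        b <- length(idx)
        Z1 <- sweep(as.matrix(X %*% W1), 2L, b1, "+")
        H <- pmax(Z1, 0)
        if (drop_p > 0) {
          mask <- matrix(stats::runif(b * ncol(H)) >= drop_p, b) / (1 - drop_p)
          Hd <- H * mask
        } else {
          mask <- NULL
          Hd <- H
        }
        p <- .sigmoid(as.numeric(Hd %*% W2) + b2)
        dz2 <- (2 / b) * (p - y) * p * (1 - p)
        gW2 <- crossprod(Hd, dz2)
        gb2 <- sum(dz2)
        dH <- outer(dz2, as.numeric(W2))    # b x hidden
        if (!is.null(mask)) dH <- dH * mask
        dZ1 <- dH * (Z1 > 0)
        gW1 <- as.matrix(Matrix::crossprod(X, dZ1))
        gb1 <- colSums(dZ1)
        t <- t + 1L
        adam <- function(g, m, v) {
          m <- b1m * m + (1 - b1m) * g
          v <- b2m * v + (1 - b2m) * g * g
          mh <- m / (1 - b1m^t)
          vh <- v / (1 - b2m^t)
          list(step = lr * mh / (sqrt(vh) + eps), m = m, v = v)
        }
        s <- adam(gW1, mom$W1, vel$W1); mom$W1 <- s$m; vel$W1 <- s$v
        W1 <- W1 - s$step
        s <- adam(gb1, mom$b1, vel$b1); mom$b1 <- s$m; vel$b1 <- s$v
        b1 <- b1 - s$step
        s <- adam(gW2, mom$W2, vel$W2); mom$W2 <- s$m; vel$W2 <- s$v
        W2 <- W2 - s$step
        s <- adam(gb2, mom$b2, vel$b2); mom$b2 <- s$m; vel$b2 <- s$v
        b2 <- b2 - s$step
      }
    }
  })
  out <- params
  out$W1 <- W1; out$b1 <- b1; out$W2 <- W2; out$b2 <- b2
  out
}

#' Save network weights to JSON
#'
#' Portable dump with a shape header; inverse of [read_egn()].
#'
#' @param params `egn_params`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_egn <- function(params, path) {
  stopifnot(inherits(params, "egn_params"))
  doc <- list(
    input_dim = params$input_dim, hidden_dim = params$hidden_dim,
    dropout_rate = params$dropout_rate, init_seed = params$init_seed,
    W1 = as.numeric(params$W1), b1 = params$b1,
    W2 = as.numeric(params$W2), b2 = params$b2
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load network weights from JSON
#'
#' @param path File written by [write_egn()].
#' @return `egn_params`.
#' @export
read_egn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      W1 = matrix(doc$W1, doc$input_dim, doc$hidden_dim),
      b1 = as.numeric(doc$b1),
      W2 = matrix(doc$W2, doc$hidden_dim, 1L),
      b2 = as.numeric(doc$b2),
      dropout_rate = doc$dropout_rate,
      init_seed = as.integer(doc$init_seed),
      input_dim = as.integer(doc$input_dim),
      hidden_dim = as.integer(doc$hidden_dim)
    ),
    class = "egn_params"
  )
}
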
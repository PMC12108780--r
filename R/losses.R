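#' Loss-term weights for the student objective
#'
#' The student network minimizes
#' \deqn{L = L_{cls} + \lambda_1 L_{mse} + \lambda_2 L_{align} +
#'   \lambda_3 L_{div}}
#' where \eqn{L_{cls}} is cross-entropy, \eqn{L_{mse}} the distillation loss
#' pulling the internally invariant half z1 toward the teacher features,
#' \eqn{L_{align}} the pairwise correlation-alignment (CORAL) loss over
#' subdomain covariances of the mutually invariant half z2, and
#' \eqn{L_{div}} the (negative) divergence between z1 and z2.
#'
#' @param lambda1,lambda2,lambda3 Non-negative weights (default 1).
#' @return An object of class \code{loss_weights}.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1) {
  w <- list(lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
            lambda3 = as.numeric(lambda3))
  if (any(vapply(w, function(v) is.na(v) || v < 0, TRUE)))
    stop("loss_weights: all lambdas must be non-negative", call. = FALSE)
  class(w) <- "loss_weights"
  w
}

#' Cross-entropy classification loss
#'
#' Mean over the batch of \code{-log p(true class)}, with probabilities
#' clipped below at 1e-12 so a confident wrong prediction stays finite.
#'
#' @param probs Matrix \code{[batch, M]} of class probabilities (rows sum
#'   to 1).
#' @param labels Integer vector of true classes in \code{[0, M)}.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (nrow(probs) != length(labels))
    stop("cross_entropy: batch size mismatch", call. = FALSE)
  if (any(labels < 0L) || any(labels >= ncol(probs)))
    stop("cross_entropy: label out of range", call. = FALSE)
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

#' Mean squared error between two equal-shaped arrays
#'
#' @param a,b Numeric arrays of identical shape.
#' @return Non-negative scalar: mean of squared element-wise differences.
#' @export
mse_loss <- function(a, b) {
  if (!identical(dim2(a), dim2(b)))
    stop("mse_loss: shape mismatch", call. = FALSE)
  mean((a - b)^2)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Unbiased sample covariance of a feature matrix
#'
#' Computes \eqn{C_i = \frac{1}{n_i - 1}\left(X_i^\top X_i -
#' \frac{1}{n_i}(\mathbf{1}^\top X_i)^\top(\mathbf{1}^\top X_i)\right)},
#' the covariance entering the correlation-alignment loss.
#'
#' @param Xi Numeric matrix \code{[n_i, d]} with \code{n_i >= 2} rows
#'   (samples) and \code{d} feature columns.
#' @return Symmetric positive semi-definite \code{[d, d]} matrix.
#' @export
feat_covariance <- function(Xi) {
  Xi <- as.matrix(Xi)
  ni <- nrow(Xi)
  if (ni < 2L)
    stop("feat_covariance: need at least 2 rows (divides by n_i - 1)",
         call. = FALSE)
  s <- colSums(Xi)
  (crossprod(Xi) - tcrossprod(s) / ni) / (ni - 1)
}

#' Pairwise correlation-alignment (CORAL) loss over subdomains
#'
#' \deqn{L_{align} = \frac{2}{N(N-1)} \sum_{i \neq j}
#'   \lVert C_i - C_j \rVert_F^2}
#' with the sum running over ordered pairs (both \eqn{(i,j)} and
#' \eqn{(j,i)}), exactly as the formula is written, so for \eqn{N = 2} the
#' loss equals \eqn{2\lVert C_1 - C_2\rVert_F^2}.
#'
#' @param features List of numeric matrices \code{[n_i, d]}, one per
#'   subdomain; all with the same \code{d} and each \code{n_i >= 2};
#'   at least 2 subdomains.
#' @return Non-negative scalar.
#' @export
coral_align <- function(features) {
  N <- length(features)
  if (N < 2L) stop("coral_align: need at least 2 subdomains", call. = FALSE)
  d <- unique(vapply(features, ncol, 0L))
  if (length(d) != 1L)
    stop("coral_align: all subdomains must share the feature dimension",
         call. = FALSE)
  covs <- lapply(features, feat_covariance)
  total <- 0
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) total <- total + sum((covs[[i]] - covs[[j]])^2)
    }
  }
  2 * total / (N * (N - 1))
}

# Gradient of coral_align w.r.t. each subdomain feature matrix.
coral_align_grad <- function(features) {
  N <- length(features)
  covs <- lapply(features, feat_covariance)
  coef <- 2 / (N * (N - 1))
  csum <- Reduce(`+`, covs)
  lapply(seq_len(N), function(i) {
    # dL/dCi over ordered pairs: 4 * coef * sum_{j != i} (Ci - Cj)
    G <- 4 * coef * (N * covs[[i]] - csum)
    Xi <- features[[i]]
    ni <- nrow(Xi)
    Xc <- sweep(Xi, 2, colMeans(Xi))
    2 / (ni - 1) * (Xc %*% G)
  })
}

#' Divergence regularizer between the two feature halves
#'
#' \deqn{L_{div} = -\lVert z_1 - z_2 \rVert_2^2} averaged over the batch;
#' always non-positive. Maximizing the squared L2 distance keeps the
#' internally invariant half z1 and the mutually invariant half z2
#' complementary rather than redundant.
#'
#' @param z1,z2 Numeric matrices \code{[batch, d]} of identical shape.
#' @return Non-positive scalar.
#' @export
divergence <- function(z1, z2) {
  if (!identical(dim2(z1), dim2(z2)))
    stop("divergence: shape mismatch", call. = FALSE)
  z1 <- rbind(z1); z2 <- rbind(z2)
  -mean(rowSums((z1 - z2)^2))
}

#' Combined student training objective
#'
#' Total loss \code{Lcls + lambda1 * Lmse(z1, teacher_feat) + lambda2 *
#' Lalign(subdomain z2) + lambda3 * Ldiv(z1, z2)} with the individual
#' components returned for logging.
#'
#' @param probs Student class probabilities \code{[batch, M]}.
#' @param labels True labels in \code{[0, M)}.
#' @param z1 Internally invariant student features \code{[batch, d]}.
#' @param teacher_feat Teacher features \code{[batch, d]} (treated as a
#'   constant target; no gradient flows into the teacher).
#' @param subdomain_z2 List of z2 feature matrices, one per subdomain.
#' @param w A [loss_weights()].
#' @param z2 Optional full-batch z2 \code{[batch, d]} for the divergence
#'   term; defaults to stacking \code{subdomain_z2}.
#' @return List with \code{total} and \code{components} (named numeric:
#'   \code{cls}, \code{mse}, \code{align}, \code{div}).
#' @export
student_total_loss <- function(probs, labels, z1, teacher_feat,
                               subdomain_z2, w, z2 = NULL) {
  stopifnot(inherits(w, "loss_weights"))
  if (is.null(z2)) z2 <- do.call(rbind, subdomain_z2)
  comp <- c(cls = cross_entropy(probs, labels),
            mse = mse_loss(z1, teacher_feat),
            align = coral_align(subdomain_z2),
            div = divergence(z1, z2))
  total <- comp[["cls"]] + w$lambda1 * comp[["mse"]] +
    w$lambda2 * comp[["align"]] + w$lambda3 * comp[["div"]]
  list(total = total, components = comp)
}
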
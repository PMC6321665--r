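#' Cost function specification
#'
#' Describes which confusion-matrix based objective the GMLVQ training run
#' maximizes. Four objectives are supported: plain classification accuracy
#' (\code{"CA"}), class-weighted accuracy (\code{"WCA"}, a weighted sum of the
#' two class recalls), the F-beta measure (\code{"F_BETA"}) and a linear
#' combination of precision and recall (\code{"PR_WEIGHTED"}). All are
#' evaluated on the soft confusion matrix (see
#' \code{\link{soft_confusion_matrix}}), which keeps them differentiable.
#'
#' @param kind One of \code{"CA"}, \code{"WCA"}, \code{"F_BETA"},
#'   \code{"PR_WEIGHTED"}.
#' @param beta Positive real, the beta of the F-beta measure (only used for
#'   \code{kind = "F_BETA"}).
#' @param class_weights Two nonnegative reals summing to 1: weight on the
#'   positive-class recall and on the negative-class recall (only for
#'   \code{"WCA"}). The default \code{c(0.75, 0.25)} up-weights the minority
#'   (EARLY) class.
#' @param pr_weights Two nonnegative reals summing to 1: weight on precision
#'   and on recall (only for \code{"PR_WEIGHTED"}).
#' @return An object of class \code{cost_spec}.
#' @examples
#' cost_spec("WCA", class_weights = c(0.75, 0.25))
#' @export
cost_spec <- function(kind = c("CA", "WCA", "F_BETA", "PR_WEIGHTED"),
                      beta = 1,
                      class_weights = c(0.75, 0.25),
                      pr_weights = c(0.5, 0.5)) {
  kind <- match.arg(kind)
  if (kind == "F_BETA" && (!is.numeric(beta) || length(beta) != 1L || beta <= 0))
    stop("`beta` must be a positive number")
  chk_w <- function(w, what) {
    if (!is.numeric(w) || length(w) != 2L || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8)
      stop(sprintf("`%s` must be two nonnegative reals summing to 1", what))
  }
  if (kind == "WCA") chk_w(class_weights, "class_weights")
  if (kind == "PR_WEIGHTED") chk_w(pr_weights, "pr_weights")
  structure(list(kind = kind, beta = beta,
                 class_weights = class_weights, pr_weights = pr_weights),
            class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  extra <- switch(x$kind,
    F_BETA = sprintf(" (beta = %g)", x$beta),
    WCA = sprintf(" (weights %g/%g)", x$class_weights[1], x$class_weights[2]),
    PR_WEIGHTED = sprintf(" (precision %g / recall %g)",
                          x$pr_weights[1], x$pr_weights[2]),
    "")
  cat("GMLVQ cost specification:", x$kind, extra, "\n")
  invisible(x)
}

#' Training configuration
#'
#' Hyperparameters of a GMLVQ training run. The defaults reproduce the
#' reference configuration used for the early-folding-residue model with one
#' prototype per class: 150 epochs, 75% of the data sampled per epoch, the
#' sigmoid steepness annealed over [1, 50], unit base learning rates and a
#' square relevance mapping (M = D).
#'
#' @param epochs Positive integer, number of training epochs.
#' @param prototypes_per_class Positive integer.
#' @param data_ratio Fraction in (0, 1] of the training points sampled
#'   (without replacement) in each epoch.
#' @param sigma_interval Numeric pair \code{c(sigma_min, sigma_max)} with
#'   \code{0 < sigma_min <= sigma_max}; the sigmoid steepness is annealed
#'   linearly from the first to the last epoch.
#' @param prototype_lr,omega_lr Positive base learning rates for prototypes
#'   and the mapping matrix; both decay linearly over the run.
#' @param learn_matrix Logical; if \code{FALSE} the mapping stays at its
#'   (scaled) identity initialization and the model reduces to plain GLVQ.
#' @param omega_dim Mapping dimension M (\code{NULL} means M = D).
#' @param seed Integer seed controlling initialization jitter and the
#'   per-epoch subsampling.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(epochs = 150L,
                         prototypes_per_class = 1L,
                         data_ratio = 0.75,
                         sigma_interval = c(1, 50),
                         prototype_lr = 1.0,
                         omega_lr = 1.0,
                         learn_matrix = TRUE,
                         omega_dim = NULL,
                         seed = 42L) {
  stopifnot(epochs >= 1, prototypes_per_class >= 1,
            data_ratio > 0, data_ratio <= 1,
            length(sigma_interval) == 2L, sigma_interval[1] > 0,
            sigma_interval[1] <= sigma_interval[2],
            prototype_lr > 0, omega_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 prototypes_per_class = as.integer(prototypes_per_class),
                 data_ratio = data_ratio,
                 sigma_interval = as.numeric(sigma_interval),
                 prototype_lr = prototype_lr,
                 omega_lr = omega_lr,
                 learn_matrix = isTRUE(learn_matrix),
                 omega_dim = if (is.null(omega_dim)) NULL else as.integer(omega_dim),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Construct a GMLVQ model object
#'
#' Low-level constructor, mostly useful for tests and for deserialization;
#' models are normally produced by \code{\link{gmlvq_train}}.
#'
#' @param prototypes K x D numeric matrix, one prototype per row, in
#'   standardized feature space.
#' @param prototype_labels Character vector of length K; every class must own
#'   at least one prototype.
#' @param omega M x D mapping matrix (M <= D).
#' @param sigma Positive sigmoid steepness used for scoring.
#' @param feature_names Character vector of length D.
#' @param center,scale Per-feature standardization parameters applied to raw
#'   data before distances are computed.
#' @param positive Label of the positive (minority) class.
#' @return An object of class \code{gmlvq_model}.
#' @export
gmlvq_model <- function(prototypes, prototype_labels, omega, sigma = 1,
                        feature_names = colnames(prototypes),
                        center = NULL, scale = NULL,
                        positive = "EARLY") {
  prototypes <- as.matrix(prototypes)
  omega <- as.matrix(omega)
  K <- nrow(prototypes); D <- ncol(prototypes)
  if (K < 2L || length(unique(prototype_labels)) < 2L)
    stop("need at least two prototypes covering two classes")
  if (length(prototype_labels) != K)
    stop("prototype_labels length must match prototype count")
  if (ncol(omega) != D) stop("omega must have D columns")
  if (nrow(omega) > D) stop("mapping dimension M must not exceed D")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(D))
  if (is.null(center)) center <- setNames(rep(0, D), feature_names)
  if (is.null(scale)) scale <- setNames(rep(1, D), feature_names)
  labs <- unique(prototype_labels)
  negative <- setdiff(labs, positive)
  if (length(negative) != 1L || !(positive %in% labs))
    stop("prototype labels must cover the positive class and exactly one other class")
  structure(list(prototypes = unname(prototypes),
                 prototype_labels = as.character(prototype_labels),
                 omega = unname(omega),
                 sigma = as.numeric(sigma),
                 feature_names = feature_names,
                 center = as.numeric(center), scale = as.numeric(scale),
                 positive = positive, negative = negative),
            class = "gmlvq_model")
}

#' @export
print.gmlvq_model <- function(x, ...) {
  cat("GMLVQ model\n")
  cat(sprintf("  %d prototypes (%s), D = %d features, mapping M = %d\n",
              nrow(x$prototypes),
              paste(sprintf("%s: %d", unique(x$prototype_labels),
                            tabulate(factor(x$prototype_labels))[
                              seq_along(unique(x$prototype_labels))]),
                    collapse = ", "),
              ncol(x$prototypes), nrow(x$omega)))
  cat(sprintf("  sigma = %g, positive class = %s\n", x$sigma, x$positive))
  infl <- feature_influence(x)
  cat("  top influences:",
      paste(sprintf("%s (%.3f)", head(infl$feature, 3), head(infl$influence, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Squared distance under a linear mapping
#'
#' Computes \eqn{d'(v, w) = \|\Omega (v - w)\|^2 = (v-w)^T \Lambda (v-w)} with
#' \eqn{\Lambda = \Omega^T \Omega}, the distance GMLVQ uses everywhere.
#'
#' @param v,w Numeric vectors of length D.
#' @param omega M x D numeric matrix.
#' @return Nonnegative scalar.
#' @examples
#' mapped_distance(c(1, 1), c(0, 0), rbind(c(2, 0), c(0, 0)))  # 4
#' @export
mapped_distance <- function(v, w, omega) {
  omega <- as.matrix(omega)
  if (length(v) != length(w) || ncol(omega) != length(v))
    stop("dimension mismatch between v, w and omega")
  u <- as.numeric(omega %*% (v - w))
  sum(u * u)
}

# Pairwise squared mapped distances between rows of X (n x D) and rows of
# W (K x D): returns n x K matrix. Negative round-off clamped at 0.
.pairwise_mapped_sq <- function(X, W, omega) {
  A <- X %*% t(omega)            # n x M
  B <- W %*% t(omega)            # K x M
  d <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d[d < 0] <- 0
  d
}

# Nearest same-class / other-class prototype distances and indices for a
# standardized data matrix. own = labels of the points ("plus" side).
# Ties broken toward the lowest prototype index (which.min semantics).
.nearest_pair <- function(X, labels, model) {
  d <- .pairwise_mapped_sq(X, model$prototypes, model$omega)
  proto_lab <- model$prototype_labels
  n <- nrow(X)
  idx_plus <- integer(n); idx_minus <- integer(n)
  d_plus <- numeric(n); d_minus <- numeric(n)
  for (lab in unique(proto_lab)) {
    own_cols <- which(proto_lab == lab)
    oth_cols <- which(proto_lab != lab)
    rows <- which(labels == lab)
    if (!length(rows)) next
    dp <- d[rows, own_cols, drop = FALSE]
    dm <- d[rows, oth_cols, drop = FALSE]
    jp <- max.col(-dp, ties.method = "first")
    jm <- max.col(-dm, ties.method = "first")
    idx_plus[rows] <- own_cols[jp]
    idx_minus[rows] <- oth_cols[jm]
    d_plus[rows] <- dp[cbind(seq_along(rows), jp)]
    d_minus[rows] <- dm[cbind(seq_along(rows), jm)]
  }
  list(d_plus = d_plus, d_minus = d_minus,
       idx_plus = idx_plus, idx_minus = idx_minus)
}

# mu from the two distances; 0 where both distances vanish.
.mu_from_d <- function(d_plus, d_minus) {
  s <- d_plus + d_minus
  mu <- ifelse(s > 0, (d_plus - d_minus) / s, 0)
  mu
}

#' Relative distance score
#'
#' The GLVQ classifier score \eqn{\mu(v) = (d^+ - d^-)/(d^+ + d^-)} where
#' \eqn{d^+} is the mapped distance to the nearest prototype carrying
#' \code{label} and \eqn{d^-} the distance to the nearest prototype of the
#' other class. \eqn{\mu \in [-1, 1]} and is negative exactly when the point
#' is classified correctly (its nearest prototype shares its label). If both
#' distances are zero the score is defined as 0. With \code{label} omitted,
#' the positive class plays the role of "own" class, giving the label-free
#' EFR-propensity variant used for prediction.
#'
#' @param v Numeric vector of length D, already in the model's standardized
#'   space.
#' @param model A \code{gmlvq_model}.
#' @param label Class label treated as v's own class; defaults to the model's
#'   positive class.
#' @return Scalar in [-1, 1].
#' @export
relative_score <- function(v, model, label = model$positive) {
  if (!label %in% model$prototype_labels)
    stop("model has no prototype labelled ", label)
  if (!all(unique(model$prototype_labels) %in% model$prototype_labels))
    stop("model must carry at least one prototype per class")
  np <- .nearest_pair(matrix(v, nrow = 1), label, model)
  .mu_from_d(np$d_plus, np$d_minus)
}

#' Logistic transfer function
#'
#' \eqn{f_\sigma(x) = 1 / (1 + e^{-\sigma x})}: maps the (negated) relative
#' score into (0, 1) so that values above 0.5 indicate correct
#' classification. Saturates cleanly on overflow.
#'
#' @param x Numeric vector.
#' @param sigma Positive steepness.
#' @return Numeric vector in (0, 1) (attaining 0/1 only at saturation).
#' @export
sigmoid_transfer <- function(x, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  1 / (1 + exp(-sigma * x))
}

#' Soft confusion matrix
#'
#' Accumulates per-point soft correctness \eqn{c(v) = f_\sigma(-\mu(v))} into
#' confusion-matrix cells: positives contribute \eqn{c} to TP and \eqn{1-c}
#' to FN, negatives contribute \eqn{c} to TN and \eqn{1-c} to FP. The
#' marginals are exact: \code{tp + fn} equals the number of positives
#' presented, \code{tn + fp} the number of negatives. As \eqn{\sigma \to
#' \infty} the soft matrix converges to the hard confusion matrix (provided
#' no point sits exactly on the decision boundary, \eqn{\mu = 0}).
#'
#' @param model A \code{gmlvq_model}.
#' @param x Numeric matrix (rows = points) or data frame of raw features; the
#'   model's standardization is applied.
#' @param labels Class labels, one per row.
#' @param sigma Steepness; defaults to the model's stored sigma.
#' @return List of class \code{soft_cm} with fields \code{tp, fn, fp, tn} and
#'   the class counts \code{n_pos, n_neg}.
#' @export
soft_confusion_matrix <- function(model, x, labels, sigma = model$sigma) {
  X <- .standardize_input(model, x)
  labels <- as.character(labels)
  if (!nrow(X)) stop("cannot evaluate a confusion matrix on empty data")
  np <- .nearest_pair(X, labels, model)
  mu <- .mu_from_d(np$d_plus, np$d_minus)
  cc <- sigmoid_transfer(-mu, sigma)
  pos <- labels == model$positive
  structure(list(tp = sum(cc[pos]), fn = sum(1 - cc[pos]),
                 tn = sum(cc[!pos]), fp = sum(1 - cc[!pos]),
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "soft_cm")
}

# Cost value and its partial derivatives with respect to the soft tp and tn
# cells (fn = n_pos - tp and fp = n_neg - tn are eliminated). Undefined
# ratios (zero denominators) contribute 0 with zero gradient.
.cost_from_soft_cm <- function(tp, tn, n_pos, n_neg, spec) {
  n <- n_pos + n_neg
  switch(spec$kind,
    CA = list(value = (tp + tn) / n, dtp = 1 / n, dtn = 1 / n),
    WCA = {
      w <- spec$class_weights
      t1 <- if (n_pos > 0) w[1] * tp / n_pos else 0
      t2 <- if (n_neg > 0) w[2] * tn / n_neg else 0
      list(value = t1 + t2,
           dtp = if (n_pos > 0) w[1] / n_pos else 0,
           dtn = if (n_neg > 0) w[2] / n_neg else 0)
    },
    F_BETA = {
      b2 <- spec$beta^2
      # denominator (1+b2) tp + b2 fn + fp simplifies to tp + b2 n_pos + n_neg - tn
      Q <- tp + b2 * n_pos + n_neg - tn
      if (Q <= 0) return(list(value = 0, dtp = 0, dtn = 0))
      list(value = (1 + b2) * tp / Q,
           dtp = (1 + b2) * (Q - tp) / Q^2,
           dtn = (1 + b2) * tp / Q^2)
    },
    PR_WEIGHTED = {
      g <- spec$pr_weights[1]
      den <- tp + n_neg - tn          # tp + fp
      re <- if (n_pos > 0) tp / n_pos else 0
      if (den <= 0) {
        list(value = (1 - g) * re, dtp = (1 - g) / n_pos, dtn = 0)
      } else {
        list(value = g * tp / den + (1 - g) * re,
             dtp = g * (den - tp) / den^2 + (1 - g) / n_pos,
             dtn = g * tp / den^2)
      }
    })
}

#' Evaluate a soft cost function
#'
#' Computes the value of the selected confusion-matrix based objective on the
#' soft confusion matrix of \code{x}. This is the quantity
#' \code{\link{gmlvq_train}} maximizes. All objectives take values in
#' [0, 1].
#'
#' @inheritParams soft_confusion_matrix
#' @param spec A \code{\link{cost_spec}}.
#' @return Scalar cost value in [0, 1].
#' @export
gmlvq_cost <- function(model, x, labels, spec = cost_spec("CA"),
                       sigma = model$sigma) {
  cm <- soft_confusion_matrix(model, x, labels, sigma = sigma)
  .cost_from_soft_cm(cm$tp, cm$tn, cm$n_pos, cm$n_neg, spec)$value
}

# Apply the model's standardization to a raw matrix / data frame, matching
# feature columns by name when available.
.standardize_input <- function(model, x) {
  if (is.data.frame(x)) {
    miss <- setdiff(model$feature_names, colnames(x))
    if (length(miss))
      stop("missing feature columns: ", paste(miss, collapse = ", "))
    x <- as.matrix(x[, model$feature_names, drop = FALSE])
  } else {
    x <- as.matrix(x)
    if (!is.null(colnames(x))) {
      miss <- setdiff(model$feature_names, colnames(x))
      if (length(miss))
        stop("missing feature columns: ", paste(miss, collapse = ", "))
      x <- x[, model$feature_names, drop = FALSE]
    } else if (ncol(x) != length(model$feature_names)) {
      stop("feature count mismatch: expected ", length(model$feature_names))
    }
  }
  storage.mode(x) <- "double"
  sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
}
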
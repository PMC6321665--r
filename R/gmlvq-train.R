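#' Train a GMLVQ model by stochastic gradient ascent
#'
#' Learns class prototypes and (optionally) the relevance mapping Omega by
#' maximizing a soft confusion-matrix objective. Each epoch draws
#' \code{ceiling(data_ratio * n)} points without replacement, accumulates the
#' exact gradient of the chosen cost through the soft correctness
#' \eqn{c(v) = f_\sigma(-\mu(v))}, the relative score \eqn{\mu} and the
#' mapped distance, takes one averaged ascent step, and renormalizes Omega to
#' \eqn{trace(\Omega^T\Omega) = 1}. The nearest same-class prototype of a
#' sampled point is attracted, the nearest other-class prototype repulsed.
#' The sigmoid steepness is annealed linearly across
#' \code{config$sigma_interval} and both learning rates decay linearly to 0
#' over the run. Prototypes start at their class mean plus a small seeded
#' jitter (sd 0.05 per standardized feature); Omega starts as a (truncated)
#' identity. Training is deterministic for a fixed seed.
#'
#' @param x Numeric matrix or data frame of raw feature rows, or a feature
#'   table containing a \code{label} column (in which case \code{labels} may
#'   be omitted).
#' @param labels Class labels, one per row.
#' @param config A \code{\link{train_config}}.
#' @param spec A \code{\link{cost_spec}}.
#' @param positive Label of the positive (minority) class.
#' @param standardize If \code{TRUE} (default) fit a z-score standardization
#'   on \code{x} (population sd; zero-variance features get divisor 1 with a
#'   warning) and store it in the model.
#' @return A \code{gmlvq_model} with attribute \code{"history"}: a data frame
#'   with one row per epoch (cost on the full training set, hard training
#'   accuracy, sigma and the learning rates used).
#' @seealso \code{\link{predict.gmlvq_model}}, \code{\link{ccm}},
#'   \code{\link{training_history}}
#' @export
gmlvq_train <- function(x, labels = NULL, config = train_config(),
                        spec = cost_spec("CA"), positive = "EARLY",
                        standardize = TRUE) {
  if (is.data.frame(x) && is.null(labels)) {
    sp <- .split_table(x)
    x <- sp$x; labels <- sp$labels
  }
  if (is.data.frame(x)) {
    fn <- intersect(.FEATURE_NAMES, colnames(x))
    if (length(fn)) x <- x[, fn, drop = FALSE]
    x <- as.matrix(x)
  }
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("labels must match rows of x")
  classes <- unique(labels)
  if (length(classes) != 2L) stop("exactly two classes are required")
  if (!positive %in% classes)
    stop("positive class ", positive, " not present in labels")
  negative <- setdiff(classes, positive)
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(ncol(X)))
  D <- ncol(X); n <- nrow(X)

  if (standardize) {
    center <- colMeans(X)
    scale <- sqrt(colMeans(sweep(X, 2, center)^2))  # population sd
    if (any(scale == 0)) {
      warning("zero-variance feature(s): ",
              paste(fnames[scale == 0], collapse = ", "),
              "; standardization divisor set to 1")
      scale[scale == 0] <- 1
    }
  } else {
    center <- rep(0, D); scale <- rep(1, D)
  }
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")

  M <- if (is.null(config$omega_dim)) D else config$omega_dim
  if (M > D) stop("omega_dim must not exceed the feature count")
  ppc <- config$prototypes_per_class
  T_ep <- config$epochs

  .with_seed(config$seed, {
    # class-mean initialization with seeded jitter
    W <- do.call(rbind, lapply(c(positive, negative), function(cl) {
      mu <- colMeans(Xs[labels == cl, , drop = FALSE])
      t(replicate(ppc, mu + rnorm(D, sd = 0.05)))
    }))
    proto_lab <- rep(c(positive, negative), each = ppc)
    omega <- diag(1, nrow = M, ncol = D)
    omega <- omega / sqrt(sum(omega^2))

    model <- gmlvq_model(W, proto_lab, omega, sigma = config$sigma_interval[1],
                         feature_names = fnames, center = center,
                         scale = scale, positive = positive)
    hist <- data.frame(epoch = integer(0), cost = numeric(0),
                       accuracy = numeric(0), sigma = numeric(0),
                       prototype_lr = numeric(0), omega_lr = numeric(0))
    n_sub <- ceiling(config$data_ratio * n)
    pos_mask <- labels == positive

    for (t_ep in seq_len(T_ep)) {
      sig <- if (T_ep == 1) config$sigma_interval[1] else
        config$sigma_interval[1] +
          (t_ep - 1) / (T_ep - 1) * diff(config$sigma_interval)
      decay <- 1 - (t_ep - 1) / T_ep
      eta_w <- config$prototype_lr * decay
      eta_o <- config$omega_lr * decay
      model$sigma <- sig

      idx <- sample.int(n, n_sub)
      Xb <- Xs[idx, , drop = FALSE]
      lb <- labels[idx]
      np <- .nearest_pair(Xb, lb, model)
      s <- np$d_plus + np$d_minus
      mu <- .mu_from_d(np$d_plus, np$d_minus)
      cc <- sigmoid_transfer(-mu, sig)

      nb_pos <- sum(lb == positive); nb_neg <- n_sub - nb_pos
      if (nb_pos == 0L || nb_neg == 0L)
        stop("epoch subsample lost a class; increase data_ratio or n")
      tp <- sum(cc[lb == positive]); tn <- sum(cc[lb != positive])
      cd <- .cost_from_soft_cm(tp, tn, nb_pos, nb_neg, spec)
      dCdc <- ifelse(lb == positive, cd$dtp, cd$dtn)

      g <- dCdc * (-sig * cc * (1 - cc))      # dCost/dmu per point
      ok <- s > 0
      a_plus <- numeric(n_sub); a_minus <- numeric(n_sub)
      a_plus[ok] <- g[ok] * 2 * np$d_minus[ok] / s[ok]^2   # dCost/dd_plus
      a_minus[ok] <- g[ok] * (-2) * np$d_plus[ok] / s[ok]^2

      if (!all(is.finite(a_plus)) || !all(is.finite(a_minus)))
        stop("non-finite gradient encountered (epoch ", t_ep, ")")

      U_plus <- Xb - model$prototypes[np$idx_plus, , drop = FALSE]
      U_minus <- Xb - model$prototypes[np$idx_minus, , drop = FALSE]
      lambda <- crossprod(model$omega)

      # prototype gradient: dCost/dw_k = -2 Lambda sum_v a_v (v - w_k)
      K <- nrow(model$prototypes)
      S <- matrix(0, K, D)
      sp1 <- rowsum(a_plus * U_plus, group = np$idx_plus)
      S[as.integer(rownames(sp1)), ] <- S[as.integer(rownames(sp1)), ] + sp1
      sm1 <- rowsum(a_minus * U_minus, group = np$idx_minus)
      S[as.integer(rownames(sm1)), ] <- S[as.integer(rownames(sm1)), ] + sm1
      gradW <- -2 * (S %*% lambda)

      if (!all(is.finite(gradW)))
        stop("non-finite prototype gradient (epoch ", t_ep, ")")
      model$prototypes <- model$prototypes + eta_w * gradW

      if (config$learn_matrix) {
        Smat <- crossprod(U_plus, a_plus * U_plus) +
          crossprod(U_minus, a_minus * U_minus)
        gradO <- 2 * (model$omega %*% Smat)
        if (!all(is.finite(gradO)))
          stop("non-finite omega gradient (epoch ", t_ep, ")")
        model$omega <- model$omega + eta_o * gradO
      }
      # trace(Omega^T Omega) = 1 after every epoch
      model$omega <- model$omega / sqrt(sum(model$omega^2))

      npf <- .nearest_pair(Xs, labels, model)
      ccf <- sigmoid_transfer(-.mu_from_d(npf$d_plus, npf$d_minus), sig)
      full_cost <- .cost_from_soft_cm(sum(ccf[pos_mask]), sum(ccf[!pos_mask]),
                                      sum(pos_mask), sum(!pos_mask), spec)$value
      pred <- .predict_standardized(model, Xs)
      hist <- rbind(hist, data.frame(
        epoch = t_ep, cost = full_cost,
        accuracy = mean(pred$label == labels),
        sigma = sig, prototype_lr = eta_w, omega_lr = eta_o))
    }
    attr(model, "history") <- hist
    attr(model, "config") <- config
    attr(model, "cost_spec") <- spec
    model
  })
}

#' Per-epoch training history
#'
#' @param model A model returned by \code{\link{gmlvq_train}}.
#' @return Data frame with columns \code{epoch}, \code{cost},
#'   \code{accuracy}, \code{sigma}, \code{prototype_lr}, \code{omega_lr}.
#' @export
training_history <- function(model) {
  h <- attr(model, "history")
  if (is.null(h)) stop("model carries no training history")
  h
}

# prediction on an already standardized matrix
.predict_standardized <- function(model, Xs) {
  pos_cols <- which(model$prototype_labels == model$positive)
  neg_cols <- which(model$prototype_labels != model$positive)
  d <- .pairwise_mapped_sq(Xs, model$prototypes, model$omega)
  d_pos <- apply(d[, pos_cols, drop = FALSE], 1, min)
  d_neg <- apply(d[, neg_cols, drop = FALSE], 1, min)
  mu_pos <- .mu_from_d(d_pos, d_neg)
  score <- sigmoid_transfer(-mu_pos, model$sigma)
  # score > 0.5 <=> nearest prototype is positive; ties go to the majority
  # (negative) class
  label <- ifelse(score > 0.5, model$positive, model$negative)
  data.frame(label = label, score = score, stringsAsFactors = FALSE)
}

#' Predict class labels and EFR-propensity scores
#'
#' Applies the model's stored standardization, assigns each row the class of
#' its nearest prototype under the mapped distance, and reports the score
#' \eqn{f_\sigma(-\mu_{pos}(v))} where \eqn{\mu_{pos}} uses the positive
#' class as "own" side. Scores above 0.5 correspond to the positive (EARLY)
#' label; exact ties go to the majority (LATE) class. Scores are monotone in
#' the negated relative score, so ranking by score is a valid ROC input.
#'
#' @param object A \code{gmlvq_model}.
#' @param newdata Matrix or data frame of raw feature rows; feature columns
#'   are matched by name when names are present.
#' @param ... Unused.
#' @return Data frame with columns \code{label} and \code{score}.
#' @export
predict.gmlvq_model <- function(object, newdata, ...) {
  Xs <- .standardize_input(object, newdata)
  .predict_standardized(object, Xs)
}

# split a feature table into matrix + labels
.split_table <- function(table) {
  if (!"label" %in% colnames(table))
    stop("feature table has no `label` column")
  feat <- intersect(.FEATURE_NAMES, colnames(table))
  if (!length(feat))
    feat <- setdiff(colnames(table), c(.ID_COLS, "label"))
  list(x = as.matrix(table[, feat, drop = FALSE]),
       labels = as.character(table$label))
}
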
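#' Classification Correlation Matrix
#'
#' Returns \eqn{\Lambda = \Omega^T \Omega}, the symmetric positive
#' semidefinite matrix through which GMLVQ measures distances. Its diagonal
#' scores the discriminative influence of single features; off-diagonal
#' entries of large magnitude mark feature pairs whose (positive or negative)
#' correlation helps separate the classes. After training the trace is 1, so
#' the diagonal is a normalized influence profile.
#'
#' @param model A \code{gmlvq_model}.
#' @return D x D symmetric matrix with feature names on both dimensions.
#' @export
ccm <- function(model) {
  lambda <- crossprod(model$omega)
  dimnames(lambda) <- list(model$feature_names, model$feature_names)
  lambda
}

#' Per-feature influence ranking
#'
#' The diagonal of the Classification Correlation Matrix, sorted in
#' decreasing order. With the trace normalized to 1 the influences sum to 1;
#' they are nonnegative by construction. The ranking is the primary
#' interpretability output of the classifier: top-ranked features contribute
#' most to class discrimination.
#'
#' @param model A \code{gmlvq_model}.
#' @return Data frame with columns \code{feature} and \code{influence},
#'   sorted by decreasing influence (stable for ties).
#' @export
feature_influence <- function(model) {
  infl <- diag(ccm(model))
  ord <- order(-infl)
  data.frame(feature = model$feature_names[ord],
             influence = unname(infl[ord]),
             stringsAsFactors = FALSE)
}

#' Two-dimensional projection of data and prototypes
#'
#' For a model trained with mapping dimension M = 2, projects data rows and
#' prototypes through Omega. Pairwise squared Euclidean distances in the
#' projection equal the mapped distances exactly, so class structure seen by
#' the classifier is displayed faithfully.
#'
#' @param model A \code{gmlvq_model} with \code{nrow(model$omega) == 2}.
#' @param x Matrix or data frame of raw feature rows.
#' @return List with \code{points} (n x 2 matrix), \code{prototypes}
#'   (K x 2 matrix) and \code{prototype_labels}.
#' @export
project_2d <- function(model, x) {
  if (nrow(model$omega) != 2L)
    stop("projection requires a model with mapping dimension M = 2")
  Xs <- .standardize_input(model, x)
  pts <- Xs %*% t(model$omega)
  prot <- model$prototypes %*% t(model$omega)
  colnames(pts) <- colnames(prot) <- c("dim1", "dim2")
  list(points = pts, prototypes = prot,
       prototype_labels = model$prototype_labels)
}
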
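#' Serialize a GMLVQ model to JSON
#'
#' Writes one JSON document holding feature names, standardization,
#' prototypes, prototype labels, the mapping matrix, sigma and (when present)
#' the training configuration and cost specification. Reals are written at
#' full precision so that a load round trip reproduces labels exactly and
#' numeric fields to within 1e-12.
#'
#' @param model A \code{gmlvq_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_gmlvq_model <- function(model, path) {
  cfg <- attr(model, "config")
  spec <- attr(model, "cost_spec")
  doc <- list(
    feature_names = model$feature_names,
    center = model$center, scale = model$scale,
    prototypes = model$prototypes,
    prototype_labels = model$prototype_labels,
    omega = model$omega,
    sigma = model$sigma,
    positive = model$positive, negative = model$negative,
    config = if (!is.null(cfg)) unclass(cfg),
    cost_spec = if (!is.null(spec)) unclass(spec))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a GMLVQ model from JSON
#'
#' @param path File written by \code{\link{write_gmlvq_model}}.
#' @return A \code{gmlvq_model}; training configuration and cost spec, if
#'   stored, are reattached as attributes.
#' @export
read_gmlvq_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- gmlvq_model(doc$prototypes, doc$prototype_labels, doc$omega,
                       sigma = doc$sigma, feature_names = doc$feature_names,
                       center = doc$center, scale = doc$scale,
                       positive = doc$positive)
  if (!is.null(doc$config))
    attr(model, "config") <- do.call(train_config, doc$config[
      c("epochs", "prototypes_per_class", "data_ratio", "sigma_interval",
        "prototype_lr", "omega_lr", "learn_matrix", "omega_dim", "seed")])
  if (!is.null(doc$cost_spec))
    attr(model, "cost_spec") <- cost_spec(doc$cost_spec$kind,
                                          beta = doc$cost_spec$beta,
                                          class_weights = doc$cost_spec$class_weights,
                                          pr_weights = doc$cost_spec$pr_weights)
  model
}

# ---- flat key=value run configuration -------------------------------------

# keys mirror the reference parameter sheet
.CONFIG_KEYS <- c("number_of_epochs", "number_of_prototypes",
                  "data_point_ratio_per_round", "sigmoid_sigma_interval",
                  "prototype_learning_rate", "matrix_learning",
                  "omega_learning_rate", "omega_dimension",
                  "cost_function", "cost_function_beta",
                  "cost_function_weights", "seed")

#' Read a flat key=value run configuration
#'
#' Parses a plain-text configuration of \code{key = value} lines (lines
#' starting with \code{#} are comments). Recognized keys:
#' \code{number_of_epochs}, \code{number_of_prototypes},
#' \code{data_point_ratio_per_round}, \code{sigmoid_sigma_interval} (e.g.
#' \code{[1.0,50.0]}), \code{prototype_learning_rate},
#' \code{matrix_learning}, \code{omega_learning_rate},
#' \code{omega_dimension}, \code{cost_function} (CA, WCA, F_BETA or
#' PR_WEIGHTED), \code{cost_function_beta}, \code{cost_function_weights}
#' (e.g. \code{[0.75,0.25]}) and \code{seed}.
#'
#' @param path Configuration file.
#' @return List with elements \code{config} (a \code{\link{train_config}})
#'   and \code{spec} (a \code{\link{cost_spec}}).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("malformed configuration line(s): ", paste(bad, collapse = "; "))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  unknown <- setdiff(keys, .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  get_val <- function(key, default = NULL) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  num_pair <- function(v) {
    if (is.null(v)) return(NULL)
    as.numeric(strsplit(gsub("[][ ]", "", v), ",")[[1]])
  }
  cfg <- train_config(
    epochs = as.integer(get_val("number_of_epochs", "150")),
    prototypes_per_class = as.integer(get_val("number_of_prototypes", "1")),
    data_ratio = as.numeric(get_val("data_point_ratio_per_round", "0.75")),
    sigma_interval = num_pair(get_val("sigmoid_sigma_interval", "[1,50]")),
    prototype_lr = as.numeric(get_val("prototype_learning_rate", "1.0")),
    omega_lr = as.numeric(get_val("omega_learning_rate", "1.0")),
    learn_matrix = toupper(get_val("matrix_learning", "TRUE")) %in%
      c("TRUE", "T", "1", "YES"),
    omega_dim = {
      od <- get_val("omega_dimension")
      if (is.null(od)) NULL else as.integer(od)
    },
    seed = as.integer(get_val("seed", "42")))
  kind <- toupper(get_val("cost_function", "CA"))
  kind <- c(F1 = "F_BETA", FBETA = "F_BETA")[kind] %|||% kind
  w <- num_pair(get_val("cost_function_weights"))
  spec <- cost_spec(kind,
                    beta = as.numeric(get_val("cost_function_beta", "1")),
                    class_weights = if (is.null(w)) c(0.75, 0.25) else w,
                    pr_weights = if (is.null(w)) c(0.5, 0.5) else w)
  list(config = cfg, spec = spec)
}

`%|||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Write a flat key=value run configuration
#'
#' @param config A \code{\link{train_config}}.
#' @param spec A \code{\link{cost_spec}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, spec, path) {
  fmt_pair <- function(v) sprintf("[%s]", paste(format(v), collapse = ","))
  lines <- c(
    sprintf("number_of_epochs = %d", config$epochs),
    sprintf("number_of_prototypes = %d", config$prototypes_per_class),
    sprintf("data_point_ratio_per_round = %s", format(config$data_ratio)),
    sprintf("sigmoid_sigma_interval = %s", fmt_pair(config$sigma_interval)),
    sprintf("prototype_learning_rate = %s", format(config$prototype_lr)),
    sprintf("matrix_learning = %s", config$learn_matrix),
    sprintf("omega_learning_rate = %s", format(config$omega_lr)),
    if (!is.null(config$omega_dim))
      sprintf("omega_dimension = %d", config$omega_dim),
    sprintf("cost_function = %s", spec$kind),
    sprintf("cost_function_beta = %s", format(spec$beta)),
    sprintf("cost_function_weights = %s",
            fmt_pair(if (spec$kind == "PR_WEIGHTED") spec$pr_weights
                     else spec$class_weights)),
    sprintf("seed = %d", config$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Write interpretation reports of a trained model
#'
#' Emits the Classification Correlation Matrix as a D x D CSV (feature names
#' as header row and first column), the influence ranking as a two-column
#' CSV, and the training history (when present) as a per-epoch CSV.
#'
#' @param model A \code{gmlvq_model}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_model_reports <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  lam <- ccm(model)
  f <- file.path(dir, "ccm.csv")
  write.csv(as.data.frame(lam), f, row.names = TRUE)
  files <- c(files, f)
  f <- file.path(dir, "influence.csv")
  write.csv(feature_influence(model), f, row.names = FALSE)
  files <- c(files, f)
  h <- attr(model, "history")
  if (!is.null(h)) {
    f <- file.path(dir, "history.csv")
    write.csv(h, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
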
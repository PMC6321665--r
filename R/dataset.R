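#' Assemble the 27-feature residue table
#'
#' Runs the full per-protein feature pipeline and returns one row per
#' residue with the canonical 27 feature columns in fixed order: energy
#' columns \code{e}/\code{ePred} (taken from the supplied table, never
#' computed internally), secondary-structure size and loop fraction,
#' relative accessible surface area, the eight typed contact counts, the
#' twelve graph centrality descriptors over the four graph representations,
#' and the two distinct neighborhood counts. Residues absent from the energy
#' table are imputed with the column mean (with a warning); if no energy
#' table is given both columns are imputed entirely (value 0, the mean of an
#' empty column, with a warning).
#'
#' @param structure A \code{protein_structure}.
#' @param protein_id Identifier stored in the table.
#' @param ss Optional 3-state secondary-structure string/vector; when
#'   \code{NULL} and no \code{dssp} is given, the dihedral fallback is used.
#' @param dssp Optional DSSP output file.
#' @param contacts Optional contact record data frame; when \code{NULL},
#'   contacts are detected geometrically.
#' @param energy Optional data frame with columns \code{chain}, \code{res},
#'   \code{e}, \code{ePred}.
#' @param conv_cutoff C-alpha distance cutoff for the Conv graph.
#' @param sasa_points Sphere sample points for the Shrake-Rupley ASA.
#' @return Data frame with id columns (\code{protein_id}, \code{chain_id},
#'   \code{seq_index}, \code{amino_acid}) and the 27 feature columns.
#' @export
assemble_features <- function(structure, protein_id = "STRUCT", ss = NULL,
                              dssp = NULL, contacts = NULL, energy = NULL,
                              conv_cutoff = 8.0, sasa_points = 960L) {
  nodes <- residue_table(structure)
  n <- nrow(nodes)
  if (!n) stop("empty structure")

  ss_states <- assign_secondary_structure(structure, dssp = dssp, ss = ss)
  ss_feat <- sec_size_and_lf(ss_states, chain = nodes$chain)
  rasa <- shrake_rupley_rasa(structure, n_points = sasa_points)

  if (is.null(contacts))
    contacts <- detect_contacts_geometric(structure, protein_id = protein_id)
  graphs <- ingest_contacts(structure, contacts)
  conv <- build_conv_graph(structure, cutoff = conv_cutoff)

  counts <- count_contacts(graphs$Plip)
  dplip <- graph_descriptors(graphs$Plip)
  dhb <- graph_descriptors(graphs$PlipHb)
  dhp <- graph_descriptors(graphs$PlipHp)
  dconv <- graph_descriptors(conv)

  e_col <- rep(NA_real_, n); ep_col <- rep(NA_real_, n)
  if (!is.null(energy)) {
    need <- c("chain", "res", "e", "ePred")
    miss <- setdiff(need, colnames(energy))
    if (length(miss))
      stop("energy table lacks column(s): ", paste(miss, collapse = ", "))
    pos <- match(paste(nodes$chain, nodes$resno, sep = "|"),
                 paste(energy$chain, energy$res, sep = "|"))
    e_col <- energy$e[pos]; ep_col <- energy$ePred[pos]
  }
  impute <- function(v, name) {
    if (!anyNA(v)) return(v)
    m <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
    warning(sum(is.na(v)), " residue(s) without ", name,
            " value; imputed with column mean ", format(m))
    v[is.na(v)] <- m
    v
  }
  e_col <- impute(e_col, "e")
  ep_col <- impute(ep_col, "ePred")

  out <- data.frame(
    protein_id = protein_id, chain_id = nodes$chain,
    seq_index = nodes$resno, amino_acid = nodes$resid,
    e = e_col, ePred = ep_col,
    SecSize = ss_feat$SecSize, LF = ss_feat$LF, Rasa = rasa$rasa,
    stringsAsFactors = FALSE)
  out <- cbind(out, counts)
  out$PlipBN <- dplip$BN; out$PlipCL <- dplip$CL; out$PlipCC <- dplip$CC
  out$PlipHbBN <- dhb$BN; out$PlipHbCL <- dhb$CL; out$PlipHbCC <- dhb$CC
  out$PlipHpBN <- dhp$BN; out$PlipHpCL <- dhp$CL; out$PlipHpCC <- dhp$CC
  out$ConvBN <- dconv$BN; out$ConvCL <- dconv$CL; out$ConvCC <- dconv$CC
  out$PlipNC <- neighborhood_count(graphs$Plip)
  out$ConvNC <- neighborhood_count(conv)
  out[, c(.ID_COLS, .FEATURE_NAMES)]
}

#' Sequence-window averaging of feature columns
#'
#' Replaces every feature value by its mean over the window of
#' \code{halfwidth} positions on each side of the residue (the residue
#' itself included), within the same protein and chain; windows are
#' truncated at chain termini. Identifier and label columns are untouched.
#'
#' @param table Feature table (rows ordered by chain and sequence position).
#' @param halfwidth Window half-width (default 4, i.e. a 9-position window).
#' @return Feature table of the same shape.
#' @export
window_average <- function(table, halfwidth = 4L) {
  if (halfwidth == 0L) return(table)
  feat <- intersect(.FEATURE_NAMES, colnames(table))
  grp <- paste(table$protein_id, table$chain_id, sep = "|")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    idx <- idx[order(table$seq_index[idx])]
    m <- as.matrix(table[idx, feat, drop = FALSE])
    nr <- nrow(m)
    sm <- matrix(0, nr, ncol(m))
    for (i in seq_len(nr)) {
      w <- max(1L, i - halfwidth):min(nr, i + halfwidth)
      sm[i, ] <- colMeans(m[w, , drop = FALSE])
    }
    table[idx, feat] <- sm
  }
  table
}

#' Attach labels and drop proline rows
#'
#' Joins per-residue EARLY/LATE labels onto the feature table and removes
#' proline rows from the labeled dataset (the experimental annotation cannot
#' cover prolines). Prolines still contribute to graphs and window averages
#' upstream; only their own rows are dropped here.
#'
#' @param table Feature table from \code{\link{assemble_features}} /
#'   \code{\link{window_average}}.
#' @param labels Either a character vector of length \code{nrow(table)} or a
#'   data frame with columns \code{protein_id}, \code{chain}, \code{res},
#'   \code{label}. Label values must be EARLY or LATE.
#' @return Labeled feature table without proline rows.
#' @export
filter_and_label <- function(table, labels) {
  if (is.data.frame(labels)) {
    need <- c("protein_id", "chain", "res", "label")
    miss <- setdiff(need, colnames(labels))
    if (length(miss))
      stop("label table lacks column(s): ", paste(miss, collapse = ", "))
    key_tab <- paste(table$protein_id, table$chain_id, table$seq_index,
                     sep = "|")
    key_lab <- paste(labels$protein_id, labels$chain, labels$res, sep = "|")
    unknown <- setdiff(key_lab, key_tab)
    if (length(unknown))
      stop("label file references unknown residues: ",
           paste(unknown, collapse = ", "))
    table$label <- NA_character_
    pos <- match(key_lab, key_tab)
    table$label[pos] <- labels$label
    table <- table[!is.na(table$label), , drop = FALSE]
  } else {
    if (length(labels) != nrow(table))
      stop("label vector length must match the table")
    table$label <- as.character(labels)
  }
  bad <- setdiff(unique(table$label), c("EARLY", "LATE"))
  if (length(bad)) stop("invalid label value(s): ", paste(bad, collapse = ", "))
  out <- table[table$amino_acid != "PRO", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Z-score standardization
#'
#' Fits a per-feature standardization (mean and population standard
#' deviation, i.e. divisor n) on the table and applies it, or applies
#' previously fitted parameters to new data. Zero-variance features get
#' divisor 1 with a warning. Refitting an already standardized table is a
#' no-op up to round-off.
#'
#' @param table Feature table.
#' @return For \code{zscore_fit}: the standardized table with attribute
#'   \code{"standardization"} (list with \code{center} and \code{scale}).
#'   For \code{zscore_apply}: the standardized table.
#' @export
zscore_fit <- function(table) {
  feat <- intersect(.FEATURE_NAMES, colnames(table))
  if (!length(feat)) feat <- colnames(table)[vapply(table, is.numeric, TRUE)]
  if (nrow(table) < 2L) stop("need at least two rows to standardize")
  m <- as.matrix(table[, feat, drop = FALSE])
  center <- colMeans(m)
  scale <- sqrt(colMeans(sweep(m, 2, center)^2))
  if (any(scale == 0)) {
    warning("zero-variance feature(s): ",
            paste(feat[scale == 0], collapse = ", "), "; divisor set to 1")
    scale[scale == 0] <- 1
  }
  params <- list(center = setNames(center, feat),
                 scale = setNames(scale, feat))
  out <- zscore_apply(params, table)
  attr(out, "standardization") <- params
  out
}

#' @param params Standardization parameters fitted by \code{zscore_fit}.
#' @rdname zscore_fit
#' @export
zscore_apply <- function(params, table) {
  feat <- names(params$center)
  miss <- setdiff(feat, colnames(table))
  if (length(miss))
    stop("table lacks standardized column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(table[, feat, drop = FALSE])
  m <- sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
  table[, feat] <- m
  table
}

# ---- ARFF / CSV I/O --------------------------------------------------------

#' Read and write feature tables in ARFF
#'
#' ARFF is the native table format of the Weka ecosystem (\code{@relation},
#' \code{@attribute ... numeric}, \code{@attribute class \{...\}},
#' \code{@data}, \code{\%} comment lines). Numeric attributes round-trip to
#' at least 1e-9; the nominal class attribute round-trips exactly and is
#' parsed case-sensitively. Attribute order is preserved.
#'
#' @param path File path.
#' @return \code{read_arff}: a data frame; the nominal class column (if
#'   named \code{class} or \code{label}) is renamed to \code{label} and kept
#'   as character.
#' @export
read_arff <- function(path) {
  df <- tryCatch(foreign::read.arff(path),
                 error = function(e) stop("failed to parse ARFF ", path, ": ",
                                          conditionMessage(e)))
  cn <- colnames(df)
  cls <- which(cn %in% c("class", "label"))
  if (length(cls)) {
    colnames(df)[cls[1]] <- "label"
    df$label <- as.character(df$label)
  }
  df
}

#' @param table Feature table; a \code{label} column becomes the nominal
#'   \code{class} attribute.
#' @param relation Relation name written to the ARFF header.
#' @rdname read_arff
#' @export
write_arff <- function(table, path, relation = "residues") {
  df <- table
  if ("label" %in% colnames(df)) {
    lab <- factor(df$label)
    df$label <- NULL
    df$class <- lab
  }
  chr <- vapply(df, is.character, TRUE)
  df[chr] <- lapply(df[chr], factor)
  foreign::write.arff(df, path, relation = relation)
  invisible(path)
}

#' Read and write feature tables as CSV
#'
#' @param path File path.
#' @return \code{read_feature_csv}: data frame with a character \code{label}
#'   column when present.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("class" %in% colnames(df) && !"label" %in% colnames(df))
    colnames(df)[colnames(df) == "class"] <- "label"
  df
}

#' @param table Feature table.
#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
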
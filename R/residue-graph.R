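#' Residue interaction graphs
#'
#' Proteins are represented as residue graphs: residues are nodes and
#' contacts are edges. Four representations are used: \code{Plip} (all
#' annotated non-covalent contacts), \code{PlipHb} (hydrogen bonds only),
#' \code{PlipHp} (hydrophobic interactions only) and \code{Conv} (C-alpha
#' distance contacts). Every representation additionally contains covalent
#' edges between sequence-adjacent residues of the same chain. Contacts
#' between residues fewer than six sequence positions apart are "local",
#' those more than five apart are "long-range"; contacts across chains are
#' classed long-range.
#'
#' @name residue_graph
NULL

# internal constructor: nodes = residue_table rows with node id; edges have
# node indices a < b, kind, backbone flag and sequence separation (NA across
# chains).
.residue_graph <- function(nodes, edges, tag) {
  if (nrow(edges)) {
    swap <- edges$a > edges$b
    tmp <- edges$a[swap]; edges$a[swap] <- edges$b[swap]; edges$b[swap] <- tmp
    edges <- edges[edges$a != edges$b, , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("a", "b", "kind")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, tag = tag),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("residue_graph [%s]: %d nodes, %d edges (%s)\n",
              x$tag, nrow(x$nodes), nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$edges$kind)),
                            as.integer(table(x$edges$kind))), collapse = ", ")))
  invisible(x)
}

.empty_edges <- function() {
  data.frame(a = integer(0), b = integer(0), kind = character(0),
             backbone = logical(0), sep = integer(0),
             stringsAsFactors = FALSE)
}

# covalent backbone edges: consecutive residues of the same chain
.covalent_edges <- function(nodes) {
  n <- nrow(nodes)
  if (n < 2L) return(.empty_edges())
  i <- seq_len(n - 1L)
  # consecutive residues of one chain; numbering gaps mark chain breaks
  same <- nodes$chain[i] == nodes$chain[i + 1L] &
    abs(nodes$resno[i + 1L] - nodes$resno[i]) <= 1L
  i <- i[same]
  if (!length(i)) return(.empty_edges())
  data.frame(a = i, b = i + 1L, kind = "covalent", backbone = TRUE,
             sep = abs(nodes$resno[i + 1L] - nodes$resno[i]),
             stringsAsFactors = FALSE)
}

.seq_separation <- function(nodes, a, b) {
  ifelse(nodes$chain[a] == nodes$chain[b],
         abs(nodes$resno[a] - nodes$resno[b]), NA_integer_)
}

#' Build the C-alpha distance contact graph
#'
#' Connects every residue pair whose C-alpha atoms are at most \code{cutoff}
#' apart (boundary inclusive); covalent edges between sequence-adjacent
#' residues are always present. Residues without a C-alpha atom are skipped
#' for distance contacts with a warning.
#'
#' @param structure A \code{protein_structure}.
#' @param cutoff Distance threshold in Angstrom (default 8.0).
#' @return A \code{residue_graph} with tag \code{"Conv"}.
#' @export
build_conv_graph <- function(structure, cutoff = 8.0) {
  nodes <- residue_table(structure)
  if (!nrow(nodes)) stop("empty structure")
  at <- structure$atoms
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "|")
  pos <- match(nodes$res_key, ca_key)
  if (anyNA(pos))
    warning(sum(is.na(pos)), " residue(s) without C-alpha skipped")
  has <- which(!is.na(pos))
  xyz <- as.matrix(ca[pos[has], c("x", "y", "z")])
  edges <- .empty_edges()
  if (length(has) >= 2L) {
    d <- as.matrix(dist(xyz))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- has[idx[, 1]]; b <- has[idx[, 2]]
      edges <- data.frame(a = a, b = b, kind = "conv", backbone = FALSE,
                          sep = .seq_separation(nodes, a, b),
                          stringsAsFactors = FALSE)
    }
  }
  cov <- .covalent_edges(nodes)
  # distance contacts that coincide with covalent neighbors stay "conv"
  # records too; the constructor dedups identical (pair, kind) rows only
  .residue_graph(nodes, rbind(cov, edges), "Conv")
}

#' Detect non-covalent contacts geometrically
#'
#' A simplified heavy-atom contact detector with documented thresholds:
#' hydrogen bonds are N/O...N/O pairs from different, non-adjacent residues
#' within 3.5 Angstrom (flagged as backbone contacts when both atoms are
#' backbone atoms N, CA, C or O); hydrophobic contacts are side-chain
#' carbon-carbon pairs within 4.0 Angstrom between apolar residues (ALA,
#' VAL, LEU, ILE, MET, PHE, TRP, PRO, TYR). One record is emitted per
#' residue pair and contact kind. Detection is heavy-atom only; structures
#' without hydrogens are the norm. Ingesting an externally computed contact
#' list (\code{\link{read_contacts}}) is the higher-fidelity path.
#'
#' @param structure A \code{protein_structure}.
#' @param hbond_cutoff Donor-acceptor heavy-atom distance (default 3.5).
#' @param hydrophobic_cutoff Carbon-carbon distance (default 4.0).
#' @param protein_id Identifier written into the records.
#' @return Contact record data frame with columns \code{protein_id},
#'   \code{chain_a}, \code{res_a}, \code{chain_b}, \code{res_b},
#'   \code{kind}, \code{backbone}.
#' @export
detect_contacts_geometric <- function(structure, hbond_cutoff = 3.5,
                                      hydrophobic_cutoff = 4.0,
                                      protein_id = "STRUCT") {
  at <- structure$atoms
  nodes <- residue_table(structure)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  node_of <- match(key, nodes$res_key)
  backbone_atoms <- c("N", "CA", "C", "O")
  apolar <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")

  pair_records <- function(sel, cutoff, kind, flag_backbone) {
    if (sum(sel) < 2L) return(NULL)
    idx <- which(sel)
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    d <- as.matrix(dist(xyz))
    hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    if (!nrow(hit)) return(NULL)
    ia <- idx[hit[, 1]]; ib <- idx[hit[, 2]]
    na <- node_of[ia]; nb <- node_of[ib]
    keep <- na != nb
    # drop pairs of covalently adjacent residues (peptide-bond geometry)
    adj <- nodes$chain[na] == nodes$chain[nb] &
      abs(nodes$resno[na] - nodes$resno[nb]) <= 1L
    keep <- keep & !adj
    if (!any(keep)) return(NULL)
    ia <- ia[keep]; ib <- ib[keep]; na <- na[keep]; nb <- nb[keep]
    bb <- if (flag_backbone)
      at$elety[ia] %in% backbone_atoms & at$elety[ib] %in% backbone_atoms
    else rep(FALSE, length(ia))
    df <- data.frame(na = pmin(na, nb), nb = pmax(na, nb), backbone = bb)
    # one record per residue pair; backbone flag if any atom pair qualifies
    agg <- stats::aggregate(backbone ~ na + nb, data = df, FUN = any)
    data.frame(protein_id = protein_id,
               chain_a = nodes$chain[agg$na], res_a = nodes$resno[agg$na],
               chain_b = nodes$chain[agg$nb], res_b = nodes$resno[agg$nb],
               kind = kind, backbone = agg$backbone,
               stringsAsFactors = FALSE)
  }

  hb_sel <- at$elesy %in% c("N", "O")
  hb <- pair_records(hb_sel, hbond_cutoff, "hbond", TRUE)
  hp_sel <- at$elesy == "C" & !(at$elety %in% backbone_atoms) &
    at$resid %in% apolar
  hp <- pair_records(hp_sel, hydrophobic_cutoff, "hydrophobic", FALSE)
  out <- rbind(hb, hp)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), chain_a = character(0),
                      res_a = integer(0), chain_b = character(0),
                      res_b = integer(0), kind = character(0),
                      backbone = logical(0), stringsAsFactors = FALSE)
  out
}

#' Read a tab-separated contact list
#'
#' Expected columns: \code{protein_id}, \code{chain_a}, \code{res_a},
#' \code{chain_b}, \code{res_b}, \code{kind} (hbond, hydrophobic or other)
#' and \code{backbone} (logical flag). Such files stand in for the output of
#' an external interaction profiler.
#'
#' @param path TSV file with a header line.
#' @return Contact record data frame.
#' @export
read_contacts <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "chain_a", "res_a", "chain_b", "res_b", "kind")
  miss <- setdiff(need, colnames(rec))
  if (length(miss))
    stop("contact list ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"backbone" %in% colnames(rec)) rec$backbone <- FALSE
  rec$backbone <- as.logical(rec$backbone)
  rec
}

#' Build the contact-based graph representations
#'
#' Turns contact records into the three contact graph representations:
#' \code{Plip} (all contact kinds), \code{PlipHb} (hydrogen bonds only) and
#' \code{PlipHp} (hydrophobic only), each with covalent backbone edges
#' added. Duplicate records collapse to a single edge; records referencing
#' residues absent from the structure are skipped with a warning listing
#' them.
#'
#' @param structure A \code{protein_structure}.
#' @param records Contact record data frame
#'   (\code{\link{detect_contacts_geometric}} / \code{\link{read_contacts}}).
#' @return Named list of \code{residue_graph}s: \code{Plip}, \code{PlipHb},
#'   \code{PlipHp}.
#' @export
ingest_contacts <- function(structure, records) {
  nodes <- residue_table(structure)
  lookup <- paste(nodes$chain, nodes$resno, sep = "|")
  cov <- .covalent_edges(nodes)
  to_edges <- function(rec) {
    if (!nrow(rec)) return(.empty_edges())
    a <- match(paste(rec$chain_a, rec$res_a, sep = "|"), lookup)
    b <- match(paste(rec$chain_b, rec$res_b, sep = "|"), lookup)
    bad <- is.na(a) | is.na(b)
    if (any(bad)) {
      refs <- unique(c(paste0(rec$chain_a, ":", rec$res_a)[bad],
                       paste0(rec$chain_b, ":", rec$res_b)[bad]))
      warning(sum(bad), " contact record(s) reference unknown residues (",
              paste(refs, collapse = ", "), "); skipped")
      rec <- rec[!bad, , drop = FALSE]; a <- a[!bad]; b <- b[!bad]
    }
    if (!nrow(rec)) return(.empty_edges())
    kind <- ifelse(rec$kind %in% c("hbond", "hydrophobic"), rec$kind, "other")
    df <- data.frame(a = pmin(a, b), b = pmax(a, b), kind = kind,
                     backbone = rec$backbone, stringsAsFactors = FALSE)
    agg <- stats::aggregate(backbone ~ a + b + kind, data = df, FUN = any)
    agg$sep <- .seq_separation(nodes, agg$a, agg$b)
    agg[, c("a", "b", "kind", "backbone", "sep")]
  }
  edges <- to_edges(records)
  list(
    Plip = .residue_graph(nodes, rbind(cov, edges), "Plip"),
    PlipHb = .residue_graph(nodes,
                            rbind(cov, edges[edges$kind == "hbond", ,
                                             drop = FALSE]), "PlipHb"),
    PlipHp = .residue_graph(nodes,
                            rbind(cov, edges[edges$kind == "hydrophobic", ,
                                             drop = FALSE]), "PlipHp"))
}

# igraph object on deduplicated residue pairs (all edge kinds, covalent
# included: covalently bound residues count as in contact)
.igraph_of <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges[!duplicated(graph$edges[, c("a", "b")]), , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = e$a, to = e$b),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Topological descriptors of a residue graph
#'
#' Computes, per node: betweenness centrality (shortest-path transit count,
#' multiple shortest paths splitting credit equally, normalized by the
#' number of node pairs \eqn{0.5 n (n-1)}); closeness centrality (inverse of
#' the average shortest-path length; in disconnected graphs the average runs
#' over reachable nodes only and isolated nodes get 0); and the clustering
#' coefficient (edges among neighbors over \eqn{0.5 n_k (n_k - 1)}, 0 for
#' degree below 2). All edges, including covalent ones, have unit weight.
#'
#' @param graph A \code{residue_graph}.
#' @return Data frame with columns \code{BN}, \code{CL}, \code{CC}, one row
#'   per node.
#' @export
graph_descriptors <- function(graph) {
  n <- nrow(graph$nodes)
  if (n == 0L) return(data.frame(BN = numeric(0), CL = numeric(0),
                                 CC = numeric(0)))
  g <- .igraph_of(graph)
  bn <- if (n < 3L) rep(0, n) else
    igraph::betweenness(g, directed = FALSE, normalized = FALSE) /
      (0.5 * n * (n - 1))
  dmat <- igraph::distances(g)
  cl <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, 0)
  cc <- suppressWarnings(igraph::transitivity(g, type = "local",
                                              isolates = "zero"))
  cc[is.nan(cc)] <- 0
  data.frame(BN = as.numeric(bn), CL = cl, CC = cc)
}

#' Distinct neighborhood count
#'
#' Counts how many sequentially distant protein regions a residue connects:
#' its non-covalent, same-chain contact partners at sequence separation
#' greater than \code{separation} are sorted by residue number and merged
#' into regions whenever consecutive partners are at most \code{separation}
#' positions apart; the region count is returned.
#'
#' @param graph A \code{residue_graph}.
#' @param separation Sequence-separation threshold (default 5).
#' @return Integer vector, one count per node.
#' @export
neighborhood_count <- function(graph, separation = 5L) {
  nodes <- graph$nodes
  e <- graph$edges[graph$edges$kind != "covalent", , drop = FALSE]
  e <- e[!duplicated(e[, c("a", "b")]), , drop = FALSE]
  out <- integer(nrow(nodes))
  if (!nrow(e)) return(out)
  for (i in seq_len(nrow(nodes))) {
    part <- c(e$b[e$a == i], e$a[e$b == i])
    part <- part[nodes$chain[part] == nodes$chain[i]]
    part <- part[abs(nodes$resno[part] - nodes$resno[i]) > separation]
    if (!length(part)) next
    rn <- sort(unique(nodes$resno[part]))
    out[i] <- 1L + sum(diff(rn) > separation)
  }
  out
}

#' Typed local and long-range contact counts
#'
#' Per-residue counts of non-covalent contacts in the \code{Plip} graph
#' family, split by kind and sequence locality: total (\code{PlipLC} /
#' \code{PlipLR}), hydrogen bonds (\code{PlipHbLC} / \code{PlipHbLR}),
#' hydrophobic (\code{PlipHpLC} / \code{PlipHpLR}) and backbone-flagged
#' contacts (\code{PlipBbLC} / \code{PlipBbLR}). Local means fewer than six
#' sequence positions apart, long-range more than five; cross-chain contacts
#' count as long-range. Covalent edges are never counted.
#'
#' @param plip_graph The \code{Plip} \code{residue_graph} (all contact
#'   kinds).
#' @return Data frame with the eight count columns, one row per node.
#' @export
count_contacts <- function(plip_graph) {
  nodes <- plip_graph$nodes
  n <- nrow(nodes)
  e <- plip_graph$edges[plip_graph$edges$kind != "covalent", , drop = FALSE]
  cols <- c("PlipLC", "PlipHbLC", "PlipHpLC", "PlipBbLC",
            "PlipLR", "PlipHbLR", "PlipHpLR", "PlipBbLR")
  out <- as.data.frame(matrix(0L, n, length(cols),
                              dimnames = list(NULL, cols)))
  if (!nrow(e)) return(out)
  local <- !is.na(e$sep) & e$sep < 6L
  add <- function(col, sel) {
    cnt <- tabulate(c(e$a[sel], e$b[sel]), nbins = n)
    out[[col]] <<- out[[col]] + cnt
  }
  add("PlipLC", local); add("PlipLR", !local)
  add("PlipHbLC", local & e$kind == "hbond")
  add("PlipHbLR", !local & e$kind == "hbond")
  add("PlipHpLC", local & e$kind == "hydrophobic")
  add("PlipHpLR", !local & e$kind == "hydrophobic")
  add("PlipBbLC", local & e$backbone)
  add("PlipBbLR", !local & e$backbone)
  out
}
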
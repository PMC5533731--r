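#' Pairwise Spearman correlation matrix
#'
#' Tie-corrected Spearman rank correlations with pairwise-complete
#' handling of missing values. Entries supported by fewer than
#' `min_pairs` complete pairs, and entries involving a constant column,
#' are marked undefined (`NA`).
#'
#' @param data numeric matrix or data frame, descriptors in columns.
#' @param min_pairs minimum complete pairs per entry (default 3).
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `"n_pairs"` carries the complete-pair counts.
#' @export
spearman_matrix <- function(data, min_pairs = 3L) {
  m <- as.matrix(data)
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  obs <- !is.na(m)
  npairs <- crossprod(obs)
  rho[npairs < min_pairs] <- NA_real_
  constant <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[!is.na(m[, j]), j]
    length(unique(v)) <= 1L
  }, logical(1L))
  if (any(constant)) {
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
  }
  diag(rho) <- 1
  attr(rho, "n_pairs") <- npairs
  rho
}

#' Threshold a correlation matrix into a descriptor network
#'
#' Retains an edge where `|rho| >= threshold` (absolute value, so
#' strongly anti-correlated scales such as MMSE vs ADAS stay linked) with
#' distance `1/|rho|`; small distance means strong correlation. Isolated
#' nodes are kept in the node list.
#'
#' @param rho_matrix symmetric correlation matrix (e.g. from
#'   [spearman_matrix()]).
#' @param threshold retention threshold on `|rho|`, inclusive
#'   (default 0.5).
#' @return a `correlation_network`: list with `nodes` (data frame:
#'   `name`, `type` baseline/slope, `class` clinical/MRI/PET/CSF/other)
#'   and `edges` (data frame: `node_a`, `node_b`, `rho`, `dist`,
#'   `n_pairs`).
#' @export
build_network <- function(rho_matrix, threshold = 0.5) {
  stopifnot(is.matrix(rho_matrix), nrow(rho_matrix) == ncol(rho_matrix))
  names_ <- colnames(rho_matrix)
  npairs <- attr(rho_matrix, "n_pairs")
  idx <- which(upper.tri(rho_matrix) & !is.na(rho_matrix) &
                 abs(rho_matrix) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = names_[idx[, 1L]],
    node_b = names_[idx[, 2L]],
    rho = rho_matrix[idx],
    dist = 1 / abs(rho_matrix[idx]),
    n_pairs = if (is.null(npairs)) rep(NA_integer_, nrow(idx)) else
      npairs[idx],
    stringsAsFactors = FALSE)
  nodes <- data.frame(
    name = names_,
    type = ifelse(startsWith(names_, "S"), "slope", "baseline"),
    class = descriptor_class(names_),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "correlation_network")
}

descriptor_class <- function(names_) {
  base <- sub("^S", "", names_)
  mri <- c("Ventricles", "Hippocampus", "WholeBrain", "Entorhinal",
           "Fusiform", "MidTemp", "ICV")
  pet <- c("FDG", "AV45")
  csf <- c("ABETA", "TAU", "PTAU")
  clin <- c("CDRSB", "ADAS11", "ADAS13", "MMSE", "MOCA", "FAQ",
            "RAVLT_immediate", "RAVLT_learning", "RAVLT_forgetting",
            "RAVLT_pforgetting")
  out <- rep("other", length(names_))
  out[base %in% mri] <- "MRI"
  out[base %in% pet] <- "PET"
  out[base %in% csf] <- "CSF"
  out[base %in% clin] <- "clinical"
  out
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges at |rho| >=", x$threshold, "\n")
  invisible(x)
}

#' Export a descriptor network for force-directed layout
#'
#' Writes the network in GraphML (default) or edge-list CSV. Node
#' attributes `type` (baseline vs slope) and `class` (clinical / MRI /
#' PET / CSF) and the edge attributes `rho`, `dist` (edge weight) are
#' preserved, ready for a Fruchterman-Reingold layout downstream.
#'
#' @param network a `correlation_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"csv"`.
#' @return the path, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "correlation_network"))
  if (format == "csv") {
    utils::write.csv(network$edges, path, row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    d = network$edges[, c("node_a", "node_b", "rho", "dist")],
    directed = FALSE, vertices = network$nodes)
  igraph::E(g)$weight <- network$edges$dist
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
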
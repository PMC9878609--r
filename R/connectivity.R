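#' Connectivity matrix from softmax membership probabilities
#'
#' Pearson correlation between the K-vectors of membership probabilities of
#' pairs of nodes. Nodes are the in-mask voxels (`level = "voxel"`) or ROIs
#' (`level = "roi"`, probability vectors averaged over each ROI's voxels),
#' ordered by network.
#'
#' @param pm a `probability_maps`.
#' @param atlas a `phantom_atlas`; required at ROI level, and used at voxel
#'   level to order and label voxels by their planted network (background
#'   voxels excluded).
#' @param level `"voxel"` or `"roi"`.
#' @return a `conn_matrix`: list with symmetric `matrix`, `node_network`
#'   (network index per node), `kind`.
#' @export
softmax_connectivity <- function(pm, atlas, level = c("roi", "voxel")) {
  level <- match.arg(level)
  nv <- prod(dim(pm$probs)[1:3])
  K <- pm$n_networks
  get_vec <- function(vox) {
    vapply(seq_len(K), function(k) mean(pm$probs[vox + (k - 1L) * nv]),
           numeric(1))
  }
  if (level == "roi") {
    ord <- order(vapply(atlas$rois, `[[`, integer(1), "network_index"))
    nodes <- lapply(atlas$rois[ord], `[[`, "voxels")
    node_network <- vapply(atlas$rois[ord], `[[`, integer(1), "network_index")
  } else {
    netv <- atlas$network_volume[which(atlas$mask)]
    vox_in <- which(atlas$mask)[netv > 0]
    ord <- order(atlas$network_volume[vox_in])
    nodes <- as.list(vox_in[ord])
    node_network <- atlas$network_volume[vox_in][ord]
  }
  V <- vapply(nodes, get_vec, numeric(K))      # K x n
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0))
    stop_rsn("degenerate_node", "%d node(s) have constant probability vectors",
             sum(sds == 0))
  M <- stats::cor(V)
  structure(list(matrix = M, node_network = node_network, kind = "softmax"),
            class = "conn_matrix")
}

#' Connectivity matrix from BOLD time series
#'
#' Pearson correlation of voxel series or ROI-mean series, nodes ordered by
#' network.
#'
#' @param scan a `bold_scan`.
#' @param atlas a `phantom_atlas`.
#' @param level `"voxel"` (ROI voxels, network-ordered) or `"roi"`
#'   (ROI-mean series).
#' @return a `conn_matrix` with `kind = "timeseries"`.
#' @export
timeseries_connectivity <- function(scan, atlas, level = c("roi", "voxel")) {
  level <- match.arg(level)
  if (level == "roi") {
    ord <- order(vapply(atlas$rois, `[[`, integer(1), "network_index"))
    series <- vapply(atlas$rois[ord],
                     function(r) rowMeans(series_matrix(scan, r$voxels)),
                     numeric(dim(scan$data)[4]))
    node_network <- vapply(atlas$rois[ord], `[[`, integer(1), "network_index")
  } else {
    netv <- atlas$network_volume[which(atlas$mask)]
    vox_in <- which(atlas$mask)[netv > 0]
    ord <- order(atlas$network_volume[vox_in])
    series <- series_matrix(scan, vox_in[ord])
    node_network <- atlas$network_volume[vox_in][ord]
  }
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0))
    stop_rsn("degenerate_series", "%d node(s) have constant series", sum(sds == 0))
  structure(list(matrix = stats::cor(series), node_network = node_network,
                 kind = "timeseries"),
            class = "conn_matrix")
}

#' Within- and between-network block means of a connectivity matrix
#'
#' Mean off-diagonal correlation within same-network blocks vs. the mean
#' over different-network blocks.
#'
#' @param cm a `conn_matrix`.
#' @return list with `within` and `between`.
#' @export
block_means <- function(cm) {
  M <- cm$matrix
  net <- cm$node_network
  same <- outer(net, net, "==")
  diag(same) <- NA                        # exclude the unit diagonal
  list(within = mean(M[which(same)], na.rm = TRUE),
       between = mean(M[which(!same)], na.rm = TRUE))
}

#' @export
print.conn_matrix <- function(x, ...) {
  bm <- block_means(x)
  cat(sprintf("conn_matrix (%s): %d nodes, within-block mean %.3f, between %.3f\n",
              x$kind, nrow(x$matrix), bm$within, bm$between))
  invisible(x)
}
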
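## Consistent vs variable DEGs: cluster expression profiles, count how
## many treatment replicates support the called direction, and label
## clusters by the replicate support of their members. A DEG is variable
## when only a minority (<= 2) of replicates carry the regulation,
## consistent when more than half do.

#' Cluster DEG expression profiles
#'
#' Profiles are median-centered log2(TMM-TPM + 1) across the contrast's
#' samples; Euclidean distance, complete linkage, tree cut at
#' \code{cutFraction} of the maximum merge height. Genes are processed in
#' lexicographic id order, so the result is independent of input order.
#'
#' @param normExpr TMM-normalized TPM matrix.
#' @param degIds ids of the DEGs to cluster (>= 2).
#' @param samples sample ids defining the profile columns (default: all).
#' @param cutFraction tree-height cut as a fraction of the maximum merge
#'   height (default 0.40).
#' @return data.frame with gene_id and cluster, with the \code{hclust}
#'   tree and cut height attached as attributes \code{"tree"} and
#'   \code{"cut_height"}.
#' @export
clusterDEGs <- function(normExpr, degIds, samples = NULL,
                        cutFraction = 0.40) {
  normExpr <- as.matrix(normExpr)
  if (length(degIds) < 2) stop("need >= 2 DEGs to cluster")
  missing <- setdiff(degIds, rownames(normExpr))
  if (length(missing)) stop("DEG(s) absent from expression matrix: ",
                            paste(head(missing, 5), collapse = ", "))
  if (is.null(samples)) samples <- colnames(normExpr)
  degIds <- sort(unique(degIds))
  prof <- log2(normExpr[degIds, samples, drop = FALSE] + 1)
  prof <- prof - apply(prof, 1, median)
  tree <- hclust(dist(prof), method = "complete")
  h <- cutFraction * max(tree$height)
  cl <- cutree(tree, h = h)
  out <- data.frame(gene_id = degIds, cluster = as.integer(cl[degIds]),
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- h
  out
}

#' Replicate support for the called direction of DEGs
#'
#' For each treatment (LPS) replicate, a DEG counts as regulated in that
#' replicate when the log2 ratio of the replicate's expression (+1)
#' against the control geometric mean (+1) has the DE direction's sign
#' and magnitude >= \code{supportLfc}. The control geometric mean is
#' taken over the raw control values (any zero makes it zero).
#'
#' @param normExpr TMM-normalized TPM matrix.
#' @param degIds DEG ids.
#' @param lpsSamples treatment replicate sample ids.
#' @param controlSamples control sample ids.
#' @param direction per-DEG direction ("up"/"down"), recycled.
#' @param supportLfc magnitude threshold (default 1, half the DEG
#'   fold-change threshold).
#' @return named integer vector: replicates supporting each DEG.
#' @export
replicateSupport <- function(normExpr, degIds, lpsSamples,
                             controlSamples, direction,
                             supportLfc = 1.0) {
  normExpr <- as.matrix(normExpr)
  direction <- rep_len(direction, length(degIds))
  if (!all(direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  x <- normExpr[degIds, lpsSamples, drop = FALSE]
  ctrl <- normExpr[degIds, controlSamples, drop = FALSE]
  gm <- apply(ctrl, 1, function(v) if (any(v == 0)) 0
                                    else exp(mean(log(v))))
  ratio <- log2((x + 1) / (gm + 1))
  up <- ratio >= supportLfc
  down <- ratio <= -supportLfc
  support <- ifelse(direction == "up", rowSums(up), rowSums(down))
  setNames(as.integer(support), degIds)
}

#' Label DEGs consistent or variable from replicate support
#'
#' In cluster mode (default) each cluster is labeled from the median
#' support of its member genes and genes inherit the cluster label; in
#' gene mode each gene is labeled from its own support. A support count
#' is consistent when strictly greater than half the number of treatment
#' replicates, variable otherwise — so with 6 replicates a support of 3
#' is variable ("more than half" is not met), and with 5 replicates a
#' support of 3 is consistent.
#'
#' @param clusters data.frame from \code{\link{clusterDEGs}}.
#' @param supportCounts named vector from \code{\link{replicateSupport}}.
#' @param nReps number of treatment replicates in the contrast.
#' @param mode \code{"cluster"} (default) or \code{"gene"}.
#' @return list with \code{genes} (data.frame: gene_id, cluster,
#'   support_count, label), \code{clusters} (cluster_id, median_support,
#'   label, n_genes) and \code{fraction_consistent}.
#' @export
labelPartition <- function(clusters, supportCounts, nReps,
                           mode = c("cluster", "gene")) {
  mode <- match.arg(mode)
  idx <- match(clusters$gene_id, names(supportCounts))
  if (anyNA(idx)) stop("support count missing for some DEGs")
  support <- as.numeric(supportCounts[idx])
  if (any(support < 0) || any(support > nReps))
    stop("support counts must lie in [0, nReps]")
  consistentRule <- function(s) s > nReps / 2
  clMed <- tapply(support, clusters$cluster, median)
  clLabel <- ifelse(consistentRule(clMed), "consistent", "variable")
  label <- if (mode == "cluster") clLabel[as.character(clusters$cluster)]
           else ifelse(consistentRule(support), "consistent", "variable")
  genes <- data.frame(gene_id = clusters$gene_id,
                      cluster = clusters$cluster,
                      support_count = as.integer(support),
                      label = as.character(label),
                      stringsAsFactors = FALSE)
  clTab <- data.frame(cluster_id = as.integer(names(clMed)),
                      median_support = as.numeric(clMed),
                      label = as.character(clLabel),
                      n_genes = as.integer(table(clusters$cluster)[
                        names(clMed)]),
                      stringsAsFactors = FALSE)
  list(genes = genes, clusters = clTab,
       fraction_consistent = mean(genes$label == "consistent"))
}
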
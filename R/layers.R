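## The three expression layers: constitutive (detected in every sample),
## individual-specific (detected in some), not expressed. Presence is
## count > 0 on the raw expected-count matrix, not on normalized values.

#' Call constitutive / individual-specific / not-expressed layers
#'
#' A gene is constitutive when its raw count is > 0 in every sample,
#' not expressed when it is 0 everywhere, individual-specific otherwise.
#' Constitutive genes additionally get a high-expression flag from
#' TMM-normalized TPM against \code{highThreshold}.
#'
#' @param counts gene x sample raw count matrix.
#' @param normExpr TMM-normalized TPM matrix, same dimensions.
#' @param highThreshold high-expression cutoff on TMM-TPM (default 10).
#' @param highRule \code{"mean"} (default): across-sample mean above the
#'   threshold; \code{"all"}: every sample above it.
#' @return data.frame with gene_id, layer, n_samples_present,
#'   mean_norm_expr, constitutive_high.
#' @export
callLayers <- function(counts, normExpr, highThreshold = 10,
                       highRule = c("mean", "all")) {
  highRule <- match.arg(highRule)
  counts <- as.matrix(counts)
  normExpr <- as.matrix(normExpr)
  if (!identical(dim(counts), dim(normExpr)))
    stop("counts and normExpr must share dimensions")
  nPresent <- rowSums(counts > 0)
  layer <- ifelse(nPresent == ncol(counts), "constitutive",
                  ifelse(nPresent == 0, "not_expressed",
                         "individual_specific"))
  meanExpr <- rowMeans(normExpr)
  high <- if (highRule == "mean") meanExpr > highThreshold
          else rowSums(normExpr > highThreshold) == ncol(normExpr)
  data.frame(gene_id = rownames(counts),
             layer = layer,
             n_samples_present = as.integer(nPresent),
             mean_norm_expr = meanExpr,
             constitutive_high = high & layer == "constitutive",
             stringsAsFactors = FALSE)
}

#' Layer fractions over a gene subset
#'
#' @param assignment output of \code{\link{callLayers}}.
#' @param geneSubset gene ids to summarize (default: all genes).
#' @return list with \code{n} per layer, \code{frac_expressed}
#'   (fractions over expressed genes, summing to 1) and \code{frac_all}
#'   (fractions over the whole subset).
#' @export
layerSummary <- function(assignment, geneSubset = NULL) {
  if (is.null(geneSubset)) geneSubset <- assignment$gene_id
  if (length(geneSubset) == 0) stop("empty gene subset")
  unknown <- setdiff(geneSubset, assignment$gene_id)
  if (length(unknown))
    stop("genes not in assignment: ", paste(head(unknown, 5),
                                            collapse = ", "))
  sub <- assignment[assignment$gene_id %in% geneSubset, ]
  n <- table(factor(sub$layer, levels = .LAYERS))
  nExpr <- sum(n[c("constitutive", "individual_specific")])
  fracExpr <- if (nExpr > 0)
    as.numeric(n[c("constitutive", "individual_specific")]) / nExpr
  else c(NA_real_, NA_real_)
  list(n = setNames(as.integer(n), names(n)),
       frac_expressed = setNames(fracExpr,
                                 c("constitutive", "individual_specific")),
       frac_all = setNames(as.numeric(n) / nrow(sub), names(n)))
}

#' Median-expression ratio of constitutive immune genes vs the rest
#'
#' Compares the median per-gene mean TMM-TPM of constitutive immune genes
#' with the median over all other constitutive genes.
#'
#' @param normExpr TMM-normalized TPM matrix.
#' @param assignment output of \code{\link{callLayers}}.
#' @param immuneFlags logical vector (named by gene or aligned to
#'   \code{normExpr} rows) flagging immune genes.
#' @return list with \code{ratio}, \code{median_immune},
#'   \code{median_other}, and group sizes.
#' @export
immuneMedianRatio <- function(normExpr, assignment, immuneFlags) {
  normExpr <- as.matrix(normExpr)
  if (!is.null(names(immuneFlags)))
    immuneFlags <- immuneFlags[match(rownames(normExpr),
                                     names(immuneFlags))]
  if (length(immuneFlags) != nrow(normExpr))
    stop("need one immune flag per gene")
  constGenes <- assignment$gene_id[assignment$layer == "constitutive"]
  isConst <- rownames(normExpr) %in% constGenes
  meanExpr <- rowMeans(normExpr)
  imm <- isConst & immuneFlags %in% TRUE
  oth <- isConst & !(immuneFlags %in% TRUE)
  if (!any(imm) || !any(oth))
    stop("need >= 1 constitutive immune and >= 1 constitutive ",
         "non-immune gene")
  mi <- median(meanExpr[imm]); mo <- median(meanExpr[oth])
  list(ratio = mi / mo, median_immune = mi, median_other = mo,
       n_immune = sum(imm), n_other = sum(oth))
}

.mutualNNPairing <- function(D, sampleInd) {
  Dm <- as.matrix(D)
  diag(Dm) <- Inf
  inds <- names(which(table(sampleInd) == 2))
  if (length(inds) < 2) stop("need >= 2 individuals with 2 samples each")
  hits <- vapply(inds, function(ind) {
    pair <- which(sampleInd == ind)
    nn1 <- which(Dm[pair[1], ] <= min(Dm[pair[1], ]) + 1e-12)
    nn2 <- which(Dm[pair[2], ] <= min(Dm[pair[2], ]) + 1e-12)
    pair[2] %in% nn1 && pair[1] %in% nn2
  }, NA)
  mean(hits)
}

#' Individuality of presence/absence repertoires
#'
#' Quantifies whether samples cluster by individual rather than by
#' timepoint, as expected when gene carriage is a property of the
#' individual. Computes Jaccard distances between sample presence vectors
#' over a gene subset (typically the individual-specific genes),
#' average-linkage hierarchical clustering, a pairing score (fraction of
#' two-sample individuals whose clone pair are mutual nearest
#' neighbours), and a permutation p-value obtained by reshuffling
#' individual labels over samples.
#'
#' @param presence gene x sample logical matrix (counts > 0).
#' @param design design data.frame (sample_id, individual_id, ...).
#' @param geneSubset gene ids to use (default: all rows).
#' @param nPermutations label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with \code{tree} (hclust), \code{pairing_score},
#'   \code{p_value}, \code{tie} (TRUE when all distances are zero, in
#'   which case the score is reported with p = 1), and
#'   \code{n_permutations}.
#' @export
individualityAnalysis <- function(presence, design, geneSubset = NULL,
                                  nPermutations = 999, seed = 1L) {
  presence <- as.matrix(presence)
  if (!is.null(geneSubset)) {
    missing <- setdiff(geneSubset, rownames(presence))
    if (length(missing)) stop("genes absent from presence matrix: ",
                              paste(head(missing, 5), collapse = ", "))
    presence <- presence[geneSubset, , drop = FALSE]
  }
  idx <- match(colnames(presence), design$sample_id)
  if (anyNA(idx)) stop("samples missing from design")
  sampleInd <- design$individual_id[idx]
  D <- dist(t(presence * 1), method = "binary")
  tree <- hclust(D, method = "average")
  if (all(D < 1e-12)) {
    return(list(tree = tree, pairing_score = NA_real_, p_value = 1,
                tie = TRUE, n_permutations = as.integer(nPermutations)))
  }
  obs <- .mutualNNPairing(D, sampleInd)
  set.seed(seed)
  perm <- vapply(seq_len(nPermutations), function(i) {
    .mutualNNPairing(D, sample(sampleInd))
  }, 0)
  p <- (1 + sum(perm >= obs)) / (1 + nPermutations)
  list(tree = tree, pairing_score = obs, p_value = p, tie = FALSE,
       n_permutations = as.integer(nPermutations))
}
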
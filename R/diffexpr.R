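## Desk-scale negative-binomial Wald test per timepoint. Deliberately not
## a reimplementation of any published DE engine: a documented
## method-of-moments dispersion with decile-trend shrinkage and a normal
## Wald test on log2 fold changes, with the study's significance
## thresholds (FDR < 0.005 and |log2FC| >= 2) applied on top.

#' Presence/absence matrix from raw counts
#' @param counts gene x sample count matrix.
#' @return logical matrix, TRUE where count > 0.
#' @export
presenceMatrix <- function(counts) as.matrix(counts) > 0

#' Method-of-moments NB dispersions with decile-trend shrinkage
#'
#' Per gene, the pooled within-group variance yields a raw moment
#' estimate \code{(s2 - mu) / mu^2} (clamped at 0), which is then shrunk
#' 50/50 toward the 10%-trimmed mean raw dispersion of the gene's
#' expression decile, and floored at 1e-8. All-zero genes get NA and are
#' excluded from testing.
#'
#' @param counts gene x sample matrix (normalized counts if size factors
#'   differ between samples).
#' @param groups factor/vector of group labels, one per sample; each group
#'   needs >= 2 samples.
#' @return numeric vector of dispersions (NA for all-zero genes).
#' @export
estimateNBDispersions <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("one group label per sample required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  n <- ncol(counts); G <- nlevels(groups)
  groupMeans <- vapply(levels(groups), function(g)
    rowMeans(counts[, groups == g, drop = FALSE]), numeric(nrow(counts)))
  fitted <- groupMeans[, as.integer(groups), drop = FALSE]
  s2 <- rowSums((counts - fitted)^2) / (n - G)
  mu <- rowMeans(groupMeans)
  raw <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, 0), NA_real_)
  ok <- !is.na(raw)
  disp <- rep(NA_real_, nrow(counts))
  if (any(ok)) {
    dec <- cut(rank(mu[ok], ties.method = "first"),
               breaks = 10, labels = FALSE)
    trend <- tapply(raw[ok], dec, mean, trim = 0.1)
    disp[ok] <- pmax(0.5 * raw[ok] + 0.5 * trend[as.character(dec)], 1e-8)
  }
  names(disp) <- rownames(counts)
  disp
}

#' Negative-binomial Wald test for one LPS-vs-control contrast
#'
#' Counts are scaled by effective size factors (library size times TMM
#' factor, rescaled to geometric mean 1); the log2 fold change is taken
#' between group means with a pseudocount, its standard error from the NB
#' variance via the delta method, the two-sided p-value from the normal
#' reference, and the FDR from Benjamini-Hochberg over tested genes.
#' Independent filtering (all-zero genes plus the lowest base-mean decile)
#' is applied before the BH correction by default and reported via a
#' message. A gene is significant when \code{fdr < alpha} and
#' \code{|log2fc| >= lfcMin}.
#'
#' @param counts gene x sample raw count matrix.
#' @param design design data.frame (sample_id, treatment, timepoint).
#' @param timepoint the timepoint to contrast (e.g. "t1h").
#' @param normFactors TMM factors from \code{\link{computeTMMFactors}}
#'   (default: computed on the contrast's columns).
#' @param alpha FDR threshold (default 0.005).
#' @param lfcMin minimum absolute log2 fold change (default 2).
#' @param pseudocount added to group means before the log ratio
#'   (default 0.5).
#' @param independentFiltering drop all-zero and bottom-decile genes
#'   before BH (default TRUE).
#' @return data.frame with gene_id, base_mean, log2fc (LPS over control),
#'   se_log2fc, stat, p, fdr, significant, direction (up/down/ns), and a
#'   \code{tested} flag (FALSE for genes removed by filtering).
#' @export
testContrast <- function(counts, design, timepoint, normFactors = NULL,
                         alpha = 0.005, lfcMin = 2, pseudocount = 0.5,
                         independentFiltering = TRUE) {
  counts <- as.matrix(counts)
  sel <- design[design$timepoint == timepoint, , drop = FALSE]
  if (nrow(sel) == 0) stop("no samples at timepoint ", timepoint)
  idx <- match(sel$sample_id, colnames(counts))
  if (anyNA(idx)) stop("design samples missing from counts")
  x <- counts[, idx, drop = FALSE]
  grpA <- sel$treatment == "LPS"      # numerator
  grpB <- sel$treatment == "control"  # denominator
  if (sum(grpA) < 2 || sum(grpB) < 2)
    stop("each treatment group needs >= 2 samples at ", timepoint)
  lib <- colSums(x)
  if (any(lib[grpA] == 0) || any(lib[grpB] == 0))
    stop("sample with all-zero library in contrast at ", timepoint)
  if (is.null(normFactors)) {
    nf <- computeTMMFactors(x)
  } else {
    nf <- normFactors[match(colnames(x), names(normFactors))]
    if (anyNA(nf)) stop("normFactors missing for contrast samples")
  }
  s <- lib * nf
  s <- s / exp(mean(log(s)))
  y <- sweep(x, 2, s, "/")

  groups <- factor(ifelse(grpA, "LPS", "control"),
                   levels = c("control", "LPS"))
  disp <- estimateNBDispersions(y, groups)
  mA <- rowMeans(y[, grpA, drop = FALSE])
  mB <- rowMeans(y[, grpB, drop = FALSE])
  baseMean <- rowMeans(y)
  lfc <- log2((mA + pseudocount) / (mB + pseudocount))

  ## delta-method SE: a count with mean m*s_j scaled by 1/s_j has variance
  ## m/s_j + phi m^2, so var(group mean) = (1/n^2) sum_j (m/s_j + phi m^2)
  phi <- ifelse(is.na(disp), 0, disp)
  varGroup <- function(m, cols) {
    sj <- s[cols]
    (m * sum(1 / sj) + phi * m^2 * length(sj)) / length(sj)^2
  }
  vA <- varGroup(mA, which(grpA))
  vB <- varGroup(mB, which(grpB))
  seLfc <- sqrt(vA / (mA + pseudocount)^2 + vB / (mB + pseudocount)^2) /
    log(2)

  allZero <- baseMean == 0
  stat <- ifelse(allZero | seLfc == 0, NA_real_, lfc / seLfc)
  p <- ifelse(is.na(stat), NA_real_, 2 * pnorm(-abs(stat)))

  tested <- !allZero & !is.na(p)
  if (independentFiltering) {
    nz <- which(tested)
    if (length(nz) >= 10) {
      cutoffBase <- quantile(baseMean[nz], 0.10)
      drop <- nz[baseMean[nz] <= cutoffBase]
      tested[drop] <- FALSE
      message(sprintf(
        "independent filtering: %d all-zero and %d low-count genes removed before BH (%d tested)",
        sum(allZero), length(drop), sum(tested)))
    }
  }
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- p.adjust(p[tested], method = "BH")
  significant <- !is.na(fdr) & fdr < alpha & abs(lfc) >= lfcMin
  direction <- ifelse(!significant, "ns", ifelse(lfc > 0, "up", "down"))
  data.frame(gene_id = rownames(counts), base_mean = baseMean,
             log2fc = lfc, se_log2fc = seLfc, stat = stat, p = p,
             fdr = fdr, tested = tested, significant = significant,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Overlap and direction consistency between two timepoint contrasts
#'
#' @param de1,de2 \code{\link{testContrast}} results over the same gene
#'   universe (e.g. 1 h and 6 h).
#' @return list with per-direction DEG counts per timepoint, shared
#'   fractions (intersection over union per direction), and the
#'   direction-conflict gene list (significant in both with opposite
#'   signs).
#' @export
timepointOverlap <- function(de1, de2) {
  if (!setequal(de1$gene_id, de2$gene_id))
    stop("contrasts must share the same gene universe")
  degs <- function(de, dir) de$gene_id[de$significant & de$direction == dir]
  sharedFrac <- function(a, b) {
    u <- union(a, b)
    if (length(u) == 0) NA_real_ else length(intersect(a, b)) / length(u)
  }
  up1 <- degs(de1, "up"); up2 <- degs(de2, "up")
  dn1 <- degs(de1, "down"); dn2 <- degs(de2, "down")
  both <- intersect(de1$gene_id[de1$significant],
                    de2$gene_id[de2$significant])
  dir1 <- de1$direction[match(both, de1$gene_id)]
  dir2 <- de2$direction[match(both, de2$gene_id)]
  list(n_up = c(length(up1), length(up2)),
       n_down = c(length(dn1), length(dn2)),
       n_total = c(length(up1) + length(dn1), length(up2) + length(dn2)),
       shared_up = sharedFrac(up1, up2),
       shared_down = sharedFrac(dn1, dn2),
       n_shared = length(both),
       conflicts = both[dir1 != dir2])
}
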
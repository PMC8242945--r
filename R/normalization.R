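## Within-sample TPM and between-sample TMM scaling. The convention
## follows the Trinity downstream pipeline: TMM factors are computed on
## the raw counts and then applied to the TPM matrix.

#' Transcripts per million from counts and effective lengths
#'
#' \code{tpm[g,s] = (count[g,s]/length[g]) / sum_g'(count[g',s]/length[g'])
#' * 1e6}; every column sums to 1e6.
#'
#' @param counts gene x sample non-negative matrix.
#' @param lengths positive effective lengths, one per gene (named vectors
#'   are matched by name).
#' @return TPM matrix with the dimnames of \code{counts}.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' computeTPM(m, c(a = 100, b = 200))[, 1]
#' @export
computeTPM <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    idx <- match(rownames(counts), names(lengths))
    if (anyNA(idx)) stop("genes missing from lengths: ",
                         paste(rownames(counts)[is.na(idx)][1:5],
                               collapse = ", "))
    lengths <- lengths[idx]
  }
  if (length(lengths) != nrow(counts))
    stop("need one length per gene")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and finite")
  rate <- counts / lengths
  denom <- colSums(rate)
  bad <- denom <= 0
  if (any(bad))
    stop("zero-sum column(s): ",
         paste(colnames(counts)[bad], collapse = ", "))
  sweep(rate, 2, denom, "/") * 1e6
}

## one pairwise TMM factor: trimmed, precision-weighted mean of M values
.tmmPair <- function(obs, ref, libObs, libRef, trimM, trimA, weighted) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop("sample shares no positive genes with the reference")
  o <- obs[pos]; r <- ref[pos]
  M <- log2((o / libObs) / (r / libRef))
  A <- (log2(o / libObs) + log2(r / libRef)) / 2
  w <- (libObs - o) / (libObs * o) + (libRef - r) / (libRef * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM &
          rank(A) >= loA & rank(A) <= hiA
  if (sum(keep) < 10) {
    warning("fewer than 10 genes survive trimming; untrimmed fallback")
    keep <- rep(TRUE, n)
  }
  f <- if (weighted) sum(M[keep] / w[keep]) / sum(1 / w[keep])
       else mean(M[keep])
  2^f
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample TMM factors on raw counts. The reference column is
#' the sample whose 75th-percentile count fraction is closest to the mean
#' of those fractions. For each sample, log2 ratios (M) and average log
#' abundances (A) against the reference are computed over genes positive
#' in both, doubly trimmed (\code{trimM} on M, \code{trimA} on A), and
#' combined by a precision-weighted mean; factors are rescaled to
#' geometric mean 1. If fewer than 10 genes survive trimming, an
#' untrimmed mean is used with a warning.
#'
#' @param counts gene x sample count matrix, >= 2 columns.
#' @param trimM two-sided trim fraction on M (default 0.30).
#' @param trimA two-sided trim fraction on A (default 0.05).
#' @param weighted use delta-method precision weights (default TRUE).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
computeTMMFactors <- function(counts, trimM = 0.30, trimA = 0.05,
                              weighted = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library with zero total count")
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  refCol <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == refCol) return(1)
    .tmmPair(counts[, j], counts[, refCol], lib[j], lib[refCol],
             trimM, trimA, weighted)
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Apply TMM factors to an expression matrix
#'
#' Divides each column by its scaling factor; exactly invertible.
#'
#' @param expr gene x sample matrix (typically TPM).
#' @param factors positive per-sample factors (matched by name when both
#'   are named).
#' @return rescaled matrix.
#' @export
applyTMM <- function(expr, factors) {
  expr <- as.matrix(expr)
  if (!is.null(names(factors)) && !is.null(colnames(expr))) {
    idx <- match(colnames(expr), names(factors))
    if (anyNA(idx)) stop("samples missing from factors")
    factors <- factors[idx]
  }
  if (length(factors) != ncol(expr)) stop("need one factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("factors must be positive and finite")
  sweep(expr, 2, factors, "/")
}

#' TMM-normalized TPM in one call
#'
#' @param counts gene x sample count matrix.
#' @param lengths per-gene effective lengths.
#' @param ... passed to \code{\link{computeTMMFactors}}.
#' @return list with \code{expr} (TMM-normalized TPM), \code{tpm},
#'   \code{factors} and \code{lib_size}.
#' @export
tmmNormalizedTPM <- function(counts, lengths, ...) {
  tpm <- computeTPM(counts, lengths)
  factors <- computeTMMFactors(counts, ...)
  list(expr = applyTMM(tpm, factors), tpm = tpm, factors = factors,
       lib_size = colSums(as.matrix(counts)))
}
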
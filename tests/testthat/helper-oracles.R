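# Independent oracles, deliberately written as straight-line logic
# distinct from the package implementation paths.

# Brute-force receptor classifier: evaluates every family's full rule
# independently (including the negated clauses), then resolves by an
# explicit precedence walk. No shared code with classifyReceptor().
oracleClassify <- function(hits, hasTM,
                           tm7 = c("PF00001", "PF00002", "PF00003",
                                   "PF10320", "PF10328"),
                           evalueMax = 1e-5) {
  accs <- character()
  if (!is.null(hits) && nrow(hits) > 0) {
    keep <- if ("evalue" %in% names(hits)) hits$evalue <= evalueMax
            else rep(TRUE, nrow(hits))
    accs <- unique(hits$accession[keep])
  }
  has <- function(a) any(a %in% accs)
  tir <- has("PF01582"); ig <- has("PF00047")
  nacht <- has("PF05729"); lrr <- has("PF13516")
  sevenTM <- has(tm7); gps <- has("PF01825")
  sat <- c(
    TLR_like = tir && ig && hasTM,
    TIR_only = tir && (!ig || !hasTM),
    NLR_bona_fide = nacht && lrr,
    NACHT_only = nacht && !lrr,
    GPCR_GPS_7TM = sevenTM && gps,
    GPCR_7TM = sevenTM && !gps,
    SRCR = has(c("PF00530", "PF15494")),
    CTLD = has("PF00059"))
  for (fam in c("TLR_like", "TIR_only", "NLR_bona_fide", "NACHT_only",
                "GPCR_GPS_7TM", "GPCR_7TM", "SRCR", "CTLD"))
    if (sat[[fam]]) return(fam)
  "none"
}

# Random annotation tables mixing rule accessions, decoys, failing
# e-values and random TM flags; exercises every branch of the rules.
randomAnnotationTable <- function(nTranscripts) {
  pool <- c("PF01582", "PF00047", "PF05729", "PF13516", "PF01825",
            "PF00059", "PF00530", "PF15494", "PF00001", "PF00002",
            "PF10320", "PF00069", "PF00400", "PF00084", "PF99999")
  ids <- sprintf("rtx%03d", seq_len(nTranscripts))
  rows <- lapply(seq_len(nTranscripts), function(i) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    acc <- sample(pool, k, replace = TRUE)
    start <- cumsum(sample(10:80, k, replace = TRUE))
    data.frame(transcript_id = ids[i], accession = acc, name = acc,
               start = start, end = start + sample(30:150, k, TRUE),
               evalue = 10^runif(k, -15, -3), stringsAsFactors = FALSE)
  })
  list(domains = do.call(rbind, rows),
       flags = data.frame(transcript_id = ids,
                          has_tm = runif(nTranscripts) < 0.5,
                          has_signal = runif(nTranscripts) < 0.3,
                          stringsAsFactors = FALSE))
}

# Straight-line TMM: literal transcription of the trimmed-mean-of-M
# formulas using order() indexing rather than rank filtering.
oracleTMM <- function(counts, trimM = 0.30, trimA = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    unname(quantile(counts[, j], 0.75)) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[ok, j]; r <- counts[ok, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
    keepM <- keepA <- rep(FALSE, n)
    keepM[order(M)[loM:hiM]] <- TRUE
    keepA[order(A)[loA:hiA]] <- TRUE
    keep <- keepM & keepA
    if (sum(keep) < 10) keep <- rep(TRUE, n)  # untrimmed fallback
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, 0)
  fac <- fac / exp(mean(log(fac)))
  setNames(fac, colnames(counts))
}

# NB counts for two equal groups with optional planted fold changes.
simulateTwoGroupCounts <- function(nGenes, nPerGroup, muMeanLog = log(100),
                                   muSdLog = 1, dispersion = 0.1,
                                   lfc = 0, nDE = 0) {
  mu <- rlnorm(nGenes, muMeanLog, muSdLog)
  fc <- rep(1, nGenes)
  deIdx <- integer()
  if (nDE > 0) {
    deIdx <- sample(nGenes, nDE)
    fc[deIdx] <- 2^(lfc * sample(c(-1, 1), nDE, replace = TRUE))
  }
  muMat <- cbind(matrix(mu, nGenes, nPerGroup),
                 matrix(mu * fc, nGenes, nPerGroup))
  counts <- matrix(rnbinom(length(muMat), mu = muMat,
                           size = 1 / dispersion),
                   nGenes, 2 * nPerGroup)
  rownames(counts) <- sprintf("g%04d", seq_len(nGenes))
  colnames(counts) <- c(sprintf("ctrl_%02d", seq_len(nPerGroup)),
                        sprintf("lps_%02d", seq_len(nPerGroup)))
  list(counts = counts,
       design = data.frame(
         sample_id = colnames(counts),
         individual_id = colnames(counts),
         treatment = rep(c("control", "LPS"), each = nPerGroup),
         timepoint = "t1h", stringsAsFactors = FALSE),
       de_genes = rownames(counts)[deIdx], mu = mu)
}
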
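## Synthetic data with planted ground truth, emulating a paired-clone LPS
## challenge: two treatments x two timepoints, the same individual sampled
## at both timepoints within a treatment (clones), distinct individuals
## across treatments.

#' Simulate the replicated clone sample design
#'
#' Builds the factorial design of the emulated experiment: per treatment a
#' distinct pool of individuals, each sampled at 1 h and 6 h (clone pieces
#' of the same individual), minus any listed dropout cells. Deterministic:
#' no randomness is involved.
#'
#' @param nIndividuals individuals per treatment arm (>= 2).
#' @param dropout data.frame with columns individual_id, treatment,
#'   timepoint naming cells to omit, or NULL.
#' @return data.frame with sample_id, individual_id, treatment
#'   (control/LPS), timepoint (t1h/t6h).
#' @examples
#' nrow(simulateDesign(6))                                   # 24 samples
#' nrow(simulateDesign(6, data.frame(individual_id = "LPS_01",
#'   treatment = "LPS", timepoint = "t6h")))                 # 23 samples
#' @export
simulateDesign <- function(nIndividuals = 6L, dropout = NULL) {
  if (nIndividuals < 2L) stop("nIndividuals must be >= 2")
  ids <- function(prefix) sprintf("%s_%02d", prefix, seq_len(nIndividuals))
  des <- expand.grid(individual_id = c(ids("CTRL"), ids("LPS")),
                     timepoint = c("t1h", "t6h"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  des$treatment <- ifelse(startsWith(des$individual_id, "LPS"),
                          "LPS", "control")
  des$sample_id <- paste(des$individual_id, des$timepoint, sep = "_")
  des <- des[order(des$treatment, des$individual_id, des$timepoint),
             c("sample_id", "individual_id", "treatment", "timepoint")]
  rownames(des) <- NULL
  if (!is.null(dropout) && nrow(dropout) > 0) {
    dk <- paste(dropout$individual_id, dropout$treatment, dropout$timepoint)
    sk <- paste(des$individual_id, des$treatment, des$timepoint)
    missing <- setdiff(dk, sk)
    if (length(missing))
      stop("dropout cells not in design: ", paste(missing, collapse = "; "))
    des <- des[!sk %in% dk, , drop = FALSE]
    cells <- expand.grid(treatment = c("control", "LPS"),
                         timepoint = c("t1h", "t6h"),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cells))) {
      n <- sum(des$treatment == cells$treatment[i] &
               des$timepoint == cells$timepoint[i])
      if (n == 0)
        stop(sprintf("dropout removed all replicates of cell %s x %s",
                     cells$treatment[i], cells$timepoint[i]))
    }
    rownames(des) <- NULL
  }
  des
}

.collapseIds <- function(x) paste(x, collapse = ",")

#' Simulate counts with planted expression layers and LPS response
#'
#' Draws a gene x sample matrix of negative-binomial counts carrying the
#' three planted layers: constitutive genes (positive mean in every
#' sample, floored at \code{muFloor} so presence is recoverable),
#' individual-specific genes (structural zeros outside a per-individual
#' carrier set shared by both clones of an individual), and silent genes
#' (all-zero rows). A configurable subset of constitutive genes responds
#' to LPS: their mean is multiplied by \code{2^(+/-effectLog2FC)} in LPS
#' samples of the gene's responder individuals only. Constitutive immune
#' genes get a multiplicative baseline boost. Gene lengths are drawn from
#' a log-normal. The RNG is seeded from \code{config@seed}; identical
#' (config, design) give identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param design a design from \code{\link{simulateDesign}}; defaults to
#'   the design implied by the config.
#' @return an \linkS4class{ImmuneExperiment} whose rowData holds the truth
#'   table (layer, is_immune, receptor_family, is_responsive,
#'   response_direction, responder_individuals, carrier_individuals) and
#'   gene lengths.
#' @export
simulateCounts <- function(config, design = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (is.null(design))
    design <- simulateDesign(config@nIndividuals, config@dropoutSamples)
  set.seed(config@seed)
  nG <- config@nGenes
  genes <- sprintf("g%05d", seq_len(nG))
  individuals <- unique(design$individual_id)
  lpsInd <- unique(design$individual_id[design$treatment == "LPS"])

  ## layer assignment: exact planted counts, shuffled over gene indices
  nConst <- round(config@fracConstitutive * nG)
  nNever <- round(config@fracNeverExpressed * nG)
  nIS <- nG - nConst - nNever
  layer <- sample(rep(c("constitutive", "individual_specific",
                        "not_expressed"), c(nConst, nIS, nNever)))

  mu <- rlnorm(nG, config@meanLogMu, config@sdLogMu)
  isConst <- layer == "constitutive"
  mu[isConst] <- pmax(mu[isConst], config@muFloor)
  mu[layer == "not_expressed"] <- 0

  isImmune <- rbinom(nG, 1, config@fracImmune) == 1
  mu[isConst & isImmune] <- mu[isConst & isImmune] * config@immuneMedianBoost

  ## carrier sets (individual-level, shared by both clones)
  carriers <- vector("list", nG)
  carriers[isConst] <- list(individuals)
  for (g in which(layer == "individual_specific")) {
    keep <- runif(length(individuals)) < config@presenceProb
    # carrier set must be a non-empty proper subset: a gene carried by
    # every individual would be constitutive by definition
    if (!any(keep)) keep[sample(length(individuals), 1L)] <- TRUE
    if (all(keep)) keep[sample(length(individuals), 1L)] <- FALSE
    carriers[[g]] <- individuals[keep]
  }

  ## LPS-responsive genes: drawn from the constitutive layer
  isResp <- rep(FALSE, nG)
  respDir <- rep(NA_character_, nG)
  responders <- vector("list", nG)
  if (config@nResponsive > 0) {
    if (sum(isConst) < config@nResponsive)
      stop("not enough constitutive genes to plant ", config@nResponsive,
           " responsive genes")
    respIdx <- sample(which(isConst), config@nResponsive)
    isResp[respIdx] <- TRUE
    pen <- rep_len(config@responderPenetrance, config@nResponsive)
    respDir[respIdx] <- ifelse(runif(config@nResponsive) < config@fracDown,
                               "down", "up")
    for (k in seq_along(respIdx)) {
      nResp <- max(1L, round(pen[k] * length(lpsInd)))
      responders[[respIdx[k]]] <- sort(sample(lpsInd, nResp))
    }
  }

  ## expected counts per sample
  muMat <- matrix(mu, nrow = nG, ncol = nrow(design),
                  dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    ind <- design$individual_id[s]
    carried <- vapply(carriers, function(cc) ind %in% cc, NA)
    muMat[!carried, s] <- 0
    if (design$treatment[s] == "LPS") {
      hit <- isResp & vapply(responders, function(r) ind %in% r, NA)
      fc <- 2^(ifelse(respDir[hit] == "up", 1, -1) * config@effectLog2FC)
      muMat[hit, s] <- muMat[hit, s] * fc
    }
  }

  counts <- matrix(
    if (config@dispersion == 0) rpois(length(muMat), lambda = muMat)
    else rnbinom(length(muMat), mu = muMat, size = 1 / config@dispersion),
    nrow = nG, dimnames = dimnames(muMat))

  lengths <- pmax(100, round(rlnorm(nG, config@lengthMeanLog,
                                    config@lengthSdLog)))
  truth <- data.frame(
    layer = layer,
    baseline_mu = mu,
    is_immune = isImmune,
    receptor_family = "none",
    is_responsive = isResp,
    response_direction = respDir,
    responder_individuals = vapply(responders, .collapseIds, ""),
    carrier_individuals = vapply(carriers, .collapseIds, ""),
    stringsAsFactors = FALSE)

  ImmuneExperiment(counts, design, lengths, rowData = truth,
                   metadata = list(config = config))
}

## minimal architectures guaranteed to satisfy exactly their own family
## under the default precedence, plus innocuous decoys
.decoyPool <- c("PF00069", "PF00400", "PF00084", "PF00008", "PF00595",
                "PF00023", "PF00620", "PF00041")

.familyArchitecture <- function(family, rs) {
  switch(family,
    TLR_like = list(acc = c(rs@tirAcc, rep(rs@igAcc, sample(1:3, 1))),
                    tm = TRUE),
    TIR_only = list(acc = rs@tirAcc, tm = FALSE),
    NLR_bona_fide = list(acc = c(rs@nachtAcc,
                                 rep(rs@lrrAcc, sample(1:4, 1))),
                         tm = FALSE),
    NACHT_only = list(acc = rs@nachtAcc, tm = FALSE),
    GPCR_GPS_7TM = list(acc = c(sample(rs@tm7Acc, 1), rs@gpsAcc),
                        tm = TRUE),
    GPCR_7TM = list(acc = sample(rs@tm7Acc, 1), tm = TRUE),
    SRCR = list(acc = rep(sample(rs@srcrAcc, 1), sample(1:3, 1)),
                tm = runif(1) < 0.5),
    CTLD = list(acc = rs@ctldAcc, tm = runif(1) < 0.5),
    none = list(acc = sample(.decoyPool, sample(1:3, 1), replace = TRUE),
                tm = runif(1) < 0.3))
}

#' Simulate a domain-annotation table with planted receptor families
#'
#' For each planted receptor gene, emits domain-hit rows forming a minimal
#' architecture that satisfies exactly its family rule; non-receptor
#' transcripts get random non-triggering decoy domains, a fraction of
#' which also carry a rule accession at a failing e-value (> cutoff) to
#' exercise the e-value filter. Deterministic given the seed.
#'
#' @param nPerFamily named integer vector of planted transcripts per
#'   family (names from the family enum, \code{none} allowed), or a single
#'   integer applied to every family plus that many \code{none}
#'   transcripts.
#' @param seed RNG seed.
#' @param ruleset the \linkS4class{ReceptorRuleset} the architectures must
#'   satisfy.
#' @param transcriptIds optional ids to use (recycled in order over the
#'   planted transcripts); defaults to synthetic ids.
#' @return list with \code{domains} (6-column hit table), \code{flags}
#'   (transcript_id, has_tm, has_signal) and \code{truth}
#'   (transcript_id, family).
#' @export
simulateAnnotations <- function(nPerFamily = 25L, seed = 1L,
                                ruleset = defaultRuleset(),
                                transcriptIds = NULL) {
  set.seed(seed)
  fams <- .FAMILIES
  if (length(nPerFamily) == 1L && is.null(names(nPerFamily)))
    nPerFamily <- setNames(rep(as.integer(nPerFamily), length(fams)), fams)
  if (is.null(names(nPerFamily)) || !all(names(nPerFamily) %in% fams))
    stop("nPerFamily must be named by family")
  planted <- rep(names(nPerFamily), nPerFamily)
  n <- length(planted)
  ids <- if (is.null(transcriptIds)) sprintf("tx%04d", seq_len(n))
         else rep_len(transcriptIds, n)
  if (anyDuplicated(ids)) stop("transcript ids must be unique")

  rows <- vector("list", n)
  tm <- logical(n)
  for (i in seq_len(n)) {
    arch <- .familyArchitecture(planted[i], ruleset)
    acc <- arch$acc
    ndec <- sample(0:2, 1)
    if (ndec > 0) acc <- c(acc, sample(.decoyPool, ndec, replace = TRUE))
    ev <- 10^runif(length(acc), -20, -6)
    ## occasional above-cutoff rule hit on non-receptor transcripts
    if (planted[i] == "none" && runif(1) < 0.3) {
      acc <- c(acc, sample(c(ruleset@tirAcc, ruleset@nachtAcc,
                             ruleset@ctldAcc, ruleset@srcrAcc), 1))
      ev <- c(ev, 10^runif(1, -4.5, -1))
    }
    ord <- sample(length(acc))
    acc <- acc[ord]; ev <- ev[ord]
    width <- sample(40:200, length(acc), replace = TRUE)
    gap <- sample(5:60, length(acc), replace = TRUE)
    start <- cumsum(gap + c(0, head(width, -1)))
    rows[[i]] <- data.frame(
      transcript_id = ids[i], accession = acc, name = acc,
      start = start, end = start + width - 1, evalue = ev,
      stringsAsFactors = FALSE)
    tm[i] <- arch$tm
  }
  list(domains = do.call(rbind, rows),
       flags = data.frame(transcript_id = ids, has_tm = tm,
                          has_signal = runif(n) < 0.3,
                          stringsAsFactors = FALSE),
       truth = data.frame(transcript_id = ids, family = planted,
                          stringsAsFactors = FALSE))
}
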
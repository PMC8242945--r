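#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median quantile rbinom rlnorm rnbinom rpois runif
#'   p.adjust pnorm hclust cutree dist sd as.dist setNames tapply
#' @importFrom utils read.delim write.table head
#' @importFrom tools md5sum
NULL

.LAYERS <- c("constitutive", "individual_specific", "not_expressed")
.FAMILIES <- c("TLR_like", "TIR_only", "NLR_bona_fide", "NACHT_only",
               "GPCR_GPS_7TM", "GPCR_7TM", "SRCR", "CTLD", "none")

#' Simulation configuration for the synthetic sponge LPS experiment
#'
#' Holds every parameter of the synthetic-data generator: the replicated
#' clone design (individuals sampled at both timepoints within a treatment,
#' never across treatments), the three planted expression layers, the
#' negative-binomial noise model, and the planted LPS response.
#'
#' @slot nIndividuals integer, individuals per treatment arm.
#' @slot nGenes integer, genes simulated.
#' @slot fracConstitutive,fracIndividualSpecific,fracNeverExpressed numeric
#'   fractions of genes in each layer; must sum to 1.
#' @slot presenceProb per-individual carriage probability for
#'   individual-specific genes.
#' @slot nResponsive number of LPS-responsive genes (drawn from the
#'   constitutive layer so the response is observable).
#' @slot responderPenetrance fraction of LPS individuals in which a
#'   responsive gene actually responds; length 1 or \code{nResponsive}
#'   (recycled across responsive genes).
#' @slot effectLog2FC planted absolute log2 fold change in responders.
#' @slot fracDown fraction of responsive genes regulated downwards.
#' @slot meanLogMu,sdLogMu log-normal parameters of baseline gene means.
#' @slot muFloor lower bound applied to constitutive baseline means so the
#'   expressed-in-all-samples rule is recoverable from counts.
#' @slot dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson sampling.
#' @slot fracImmune fraction of genes flagged immune.
#' @slot immuneMedianBoost multiplicative boost on baseline means of
#'   constitutive immune genes.
#' @slot nReceptorsPerFamily planted receptor genes per PRR family.
#' @slot lengthMeanLog,lengthSdLog log-normal parameters for gene lengths.
#' @slot seed integer RNG seed.
#' @slot dropoutSamples data.frame with columns individual_id, treatment,
#'   timepoint naming design cells to omit.
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer",
    nGenes = "integer",
    fracConstitutive = "numeric",
    fracIndividualSpecific = "numeric",
    fracNeverExpressed = "numeric",
    presenceProb = "numeric",
    nResponsive = "integer",
    responderPenetrance = "numeric",
    effectLog2FC = "numeric",
    fracDown = "numeric",
    meanLogMu = "numeric",
    sdLogMu = "numeric",
    muFloor = "numeric",
    dispersion = "numeric",
    fracImmune = "numeric",
    immuneMedianBoost = "numeric",
    nReceptorsPerFamily = "integer",
    lengthMeanLog = "numeric",
    lengthSdLog = "numeric",
    seed = "integer",
    dropoutSamples = "data.frame"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(object@fracConstitutive, object@fracIndividualSpecific,
          object@fracNeverExpressed)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    msg <- c(msg, "layer fractions must lie in [0, 1]")
  else if (abs(sum(fr) - 1) > 1e-9)
    msg <- c(msg, "layer fractions must sum to 1 (tolerance 1e-9)")
  if (object@nIndividuals < 2L)
    msg <- c(msg, "nIndividuals must be >= 2")
  if (object@nGenes < 1L)
    msg <- c(msg, "nGenes must be >= 1")
  if (!is.finite(object@dispersion) || object@dispersion < 0)
    msg <- c(msg, "dispersion must be finite and >= 0")
  if (object@nResponsive > object@nGenes)
    msg <- c(msg, "nResponsive must not exceed nGenes")
  pen <- object@responderPenetrance
  if (!(length(pen) == 1L || length(pen) == object@nResponsive))
    msg <- c(msg, "responderPenetrance must have length 1 or nResponsive")
  if (any(pen < 0) || any(pen > 1))
    msg <- c(msg, "responderPenetrance values must lie in [0, 1]")
  for (p in c("presenceProb", "fracDown", "fracImmune")) {
    v <- slot(object, p)
    if (!is.finite(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  for (p in c("effectLog2FC", "meanLogMu", "sdLogMu", "muFloor",
              "immuneMedianBoost", "lengthMeanLog", "lengthSdLog")) {
    if (!is.finite(slot(object, p)))
      msg <- c(msg, sprintf("%s must be finite", p))
  }
  dd <- object@dropoutSamples
  if (nrow(dd) > 0 &&
      !all(c("individual_id", "treatment", "timepoint") %in% names(dd)))
    msg <- c(msg,
      "dropoutSamples needs columns individual_id, treatment, timepoint")
  if (length(msg)) msg else TRUE
})

#' Construct a \linkS4class{SimulationConfig}
#'
#' Defaults reproduce the study design the generator emulates: 2 treatments
#' x 2 timepoints x 6 individuals per treatment with one LPS individual
#' missing at 6 h (23 samples), a 40/45/15 constitutive /
#' individual-specific / silent layer split, NB counts with dispersion 0.2,
#' 200 LPS-responsive genes at |log2FC| = 3 with 60% down-regulation, and a
#' 1.35x median boost on constitutive immune genes.
#'
#' @param nIndividuals individuals per treatment arm.
#' @param nGenes number of genes.
#' @param fracConstitutive,fracIndividualSpecific,fracNeverExpressed layer
#'   fractions (must sum to 1).
#' @param presenceProb per-individual carriage probability.
#' @param nResponsive number of planted LPS-responsive genes.
#' @param responderPenetrance fraction of LPS individuals responding, per
#'   responsive gene (scalar or vector of length \code{nResponsive}).
#' @param effectLog2FC planted absolute log2 fold change.
#' @param fracDown fraction of responsive genes that are down-regulated.
#' @param meanLogMu,sdLogMu log-normal baseline mean parameters.
#' @param muFloor floor on constitutive baseline means.
#' @param dispersion NB dispersion; 0 = Poisson.
#' @param fracImmune fraction of genes flagged immune.
#' @param immuneMedianBoost boost factor for constitutive immune means.
#' @param nReceptorsPerFamily planted receptors per PRR family.
#' @param lengthMeanLog,lengthSdLog log-normal gene-length parameters.
#' @param seed RNG seed.
#' @param dropoutSamples data.frame of design cells to drop
#'   (individual_id, treatment, timepoint).
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- SimulationConfig(nGenes = 500, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(nIndividuals = 6L,
                             nGenes = 20000L,
                             fracConstitutive = 0.40,
                             fracIndividualSpecific = 0.45,
                             fracNeverExpressed = 0.15,
                             presenceProb = 0.5,
                             nResponsive = 200L,
                             responderPenetrance = 1.0,
                             effectLog2FC = 3,
                             fracDown = 0.6,
                             meanLogMu = log(50),
                             sdLogMu = 1,
                             muFloor = 20,
                             dispersion = 0.2,
                             fracImmune = 0.10,
                             immuneMedianBoost = 1.35,
                             nReceptorsPerFamily = 25L,
                             lengthMeanLog = log(1500),
                             lengthSdLog = 0.5,
                             seed = 1L,
                             dropoutSamples = data.frame(
                               individual_id = "LPS_01",
                               treatment = "LPS",
                               timepoint = "t6h")) {
  new("SimulationConfig",
      nIndividuals = as.integer(nIndividuals),
      nGenes = as.integer(nGenes),
      fracConstitutive = fracConstitutive,
      fracIndividualSpecific = fracIndividualSpecific,
      fracNeverExpressed = fracNeverExpressed,
      presenceProb = presenceProb,
      nResponsive = as.integer(nResponsive),
      responderPenetrance = responderPenetrance,
      effectLog2FC = effectLog2FC,
      fracDown = fracDown,
      meanLogMu = meanLogMu,
      sdLogMu = sdLogMu,
      muFloor = muFloor,
      dispersion = dispersion,
      fracImmune = fracImmune,
      immuneMedianBoost = immuneMedianBoost,
      nReceptorsPerFamily = as.integer(nReceptorsPerFamily),
      lengthMeanLog = lengthMeanLog,
      lengthSdLog = lengthSdLog,
      seed = as.integer(seed),
      dropoutSamples = if (is.null(dropoutSamples)) {
        data.frame(individual_id = character(), treatment = character(),
                   timepoint = character())
      } else dropoutSamples)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  design : %d individuals/treatment x 2 treatments x 2 timepoints (%d dropout cells)\n",
              object@nIndividuals, nrow(object@dropoutSamples)))
  cat(sprintf("  genes  : %d (constitutive %.2f / individual-specific %.2f / silent %.2f)\n",
              object@nGenes, object@fracConstitutive,
              object@fracIndividualSpecific, object@fracNeverExpressed))
  cat(sprintf("  noise  : NB dispersion %.3g, baseline lognormal(%.2f, %.2f), mu floor %g\n",
              object@dispersion, object@meanLogMu, object@sdLogMu,
              object@muFloor))
  cat(sprintf("  LPS    : %d responsive genes, |log2FC| %g, penetrance %s, %d%% down\n",
              object@nResponsive, object@effectLog2FC,
              paste(signif(unique(object@responderPenetrance), 3),
                    collapse = "/"),
              round(100 * object@fracDown)))
  cat(sprintf("  seed   : %d\n", object@seed))
})

#' Experiment container for the layered immune expression analysis
#'
#' A \linkS4class{SummarizedExperiment} with a \code{counts} assay
#' (non-negative RSEM-style expected counts), per-gene metadata in
#' \code{rowData} (at minimum \code{gene_length}; synthetic data adds the
#' planted truth columns), and the sample design in \code{colData}
#' (\code{individual_id}, \code{treatment}, \code{timepoint}).
#'
#' @export
setClass("ImmuneExperiment", contains = "SummarizedExperiment")

setValidity("ImmuneExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  need <- c("individual_id", "treatment", "timepoint")
  if (!all(need %in% names(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData needs columns",
                        paste(need, collapse = ", ")))
  if (!"gene_length" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData needs a gene_length column")
  if (length(msg)) msg else TRUE
})

#' Construct an \linkS4class{ImmuneExperiment}
#'
#' @param counts gene x sample matrix of non-negative counts with dimnames.
#' @param design data.frame with sample_id, individual_id, treatment,
#'   timepoint; rows matched to count columns by sample_id.
#' @param geneLengths numeric vector of effective lengths, one per gene.
#' @param rowData optional extra per-gene columns (e.g. a truth table).
#' @param metadata optional list stored in the object metadata.
#' @return an \linkS4class{ImmuneExperiment}.
#' @export
ImmuneExperiment <- function(counts, design, geneLengths,
                             rowData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample dimnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample ids in counts")
  idx <- match(colnames(counts), design$sample_id)
  if (anyNA(idx))
    stop("samples missing from design: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(design[idx, , drop = FALSE])
  rownames(cd) <- colnames(counts)
  if (length(geneLengths) != nrow(counts))
    stop("geneLengths must have one entry per gene")
  rd <- S4Vectors::DataFrame(gene_length = as.numeric(geneLengths))
  if (!is.null(rowData)) rd <- cbind(rd, S4Vectors::DataFrame(rowData))
  rownames(rd) <- rownames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = metadata)
  new("ImmuneExperiment", se)
}

setMethod("show", "ImmuneExperiment", function(object) {
  callNextMethod()
  rd <- SummarizedExperiment::rowData(object)
  if ("layer" %in% names(rd)) {
    tab <- table(factor(rd$layer, levels = .LAYERS))
    cat(sprintf("planted layers: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  }
})

#' Sample design of an \linkS4class{ImmuneExperiment}
#' @param x an ImmuneExperiment.
#' @return data.frame with sample_id, individual_id, treatment, timepoint.
#' @export
designTable <- function(x) {
  stopifnot(is(x, "ImmuneExperiment"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd$sample_id <- colnames(x)
  rownames(cd) <- NULL
  cd[, c("sample_id", "individual_id", "treatment", "timepoint")]
}

#' Per-gene effective lengths
#' @param x an ImmuneExperiment.
#' @return named numeric vector.
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "ImmuneExperiment"))
  setNames(SummarizedExperiment::rowData(x)$gene_length, rownames(x))
}

#' Planted truth table of a synthetic experiment
#' @param x an ImmuneExperiment produced by \code{\link{simulateCounts}}.
#' @return data.frame of planted per-gene labels.
#' @export
truthTable <- function(x) {
  stopifnot(is(x, "ImmuneExperiment"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  if (!"layer" %in% names(rd))
    stop("no planted truth in this experiment (not simulated data?)")
  rd$gene_id <- rownames(rd)
  rownames(rd) <- NULL
  rd[, c("gene_id", setdiff(names(rd), c("gene_id", "gene_length")))]
}

#' Raw counts accessor
#' @param x an ImmuneExperiment.
#' @return numeric matrix of counts.
#' @export
countsMatrix <- function(x) {
  stopifnot(is(x, "ImmuneExperiment"))
  SummarizedExperiment::assay(x, "counts")
}
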
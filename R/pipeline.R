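## Orchestration: simulate (or load) -> screen -> normalize -> layers ->
## DE per timepoint -> consistent/variable partition, with every stage
## result written as a plain tab-separated or JSON file so each
## rule can be audited independently.

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeMatrixTSV <- function(m, path, idCol = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idCol
  .writeTSV(df, path)
}

#' Read a gene x sample tab-separated matrix
#' @param path file whose first column holds gene ids.
#' @return numeric matrix with dimnames.
#' @export
readCountsMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Validate a bundle of pipeline input files
#'
#' Cross-checks counts, gene lengths, design and (optionally) domain
#' tables for shared identifiers. Fatal problems (samples in the matrix
#' absent from the design, genes without lengths) raise an error; softer
#' issues are returned as warnings.
#'
#' @param paths named list/vector with elements \code{counts},
#'   \code{lengths}, \code{design} and optionally \code{domains},
#'   \code{flags}.
#' @return list with \code{fatal} (character, empty on success) and
#'   \code{warnings}; errors are raised for fatal issues.
#' @export
validateInputs <- function(paths) {
  for (p in unlist(paths)) if (!file.exists(p)) stop("missing file: ", p)
  counts <- readCountsMatrix(paths$counts)
  lengths <- read.delim(paths$lengths, stringsAsFactors = FALSE)
  design <- read.delim(paths$design, stringsAsFactors = FALSE)
  fatal <- character(); warn <- character()
  missSamp <- setdiff(colnames(counts), design$sample_id)
  if (length(missSamp))
    fatal <- c(fatal, paste("samples in matrix absent from design:",
                            paste(missSamp, collapse = ", ")))
  missLen <- setdiff(rownames(counts), lengths[[1]])
  if (length(missLen))
    fatal <- c(fatal, paste(length(missLen), "genes lack lengths, e.g.",
                            paste(head(missLen, 3), collapse = ", ")))
  extra <- setdiff(design$sample_id, colnames(counts))
  if (length(extra))
    warn <- c(warn, paste("design samples without matrix columns:",
                          paste(extra, collapse = ", ")))
  if (!is.null(paths$domains)) {
    dom <- readDomainTable(paths$domains)
    orphan <- setdiff(dom$transcript_id, rownames(counts))
    if (length(orphan))
      warn <- c(warn, paste(length(orphan),
                            "domain-table transcripts not in matrix"))
  }
  if (length(fatal)) stop(paste(fatal, collapse = "\n"))
  list(fatal = fatal, warnings = warn)
}

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the full layered immune expression pipeline
#'
#' Simulates (or loads) the inputs, screens the transcriptome for PRR
#' families, computes TMM-normalized TPM, calls expression layers and the
#' individuality statistics, tests LPS vs control per timepoint, and
#' partitions DEGs into consistent/variable sets. Exactly one of
#' \code{simConfig} and \code{inputPaths} must be given. All stage
#' outputs are written under \code{outdir}; the returned report carries
#' the headline numbers plus per-file MD5 digests, so re-running with the
#' same configuration and seed is byte-reproducible (timings excluded).
#'
#' @param simConfig a \linkS4class{SimulationConfig}, or NULL.
#' @param inputPaths named list (counts, lengths, design, domains, flags,
#'   optionally immune_flags), or NULL.
#' @param outdir output directory (created if needed).
#' @param alpha,lfcMin DEG thresholds (defaults 0.005 and 2).
#' @param highThreshold high-expression TMM-TPM cutoff (default 10).
#' @param cutFraction DEG cluster tree cut (default 0.40).
#' @param supportLfc replicate-support log2 threshold (default 1).
#' @param nPermutations individuality permutations (default 999).
#' @param ruleset PRR \linkS4class{ReceptorRuleset}.
#' @return the run report (named list), also written as
#'   \code{report.json} in \code{outdir}.
#' @export
runPipeline <- function(simConfig = NULL, inputPaths = NULL,
                        outdir = tempfile("immuneLayers_run"),
                        alpha = 0.005, lfcMin = 2, highThreshold = 10,
                        cutFraction = 0.40, supportLfc = 1.0,
                        nPermutations = 999,
                        ruleset = defaultRuleset()) {
  if (is.null(simConfig) == is.null(inputPaths))
    stop("exactly one of simConfig and inputPaths must be supplied")
  stopifnot(alpha > 0, lfcMin > 0, highThreshold > 0, cutFraction > 0,
            supportLfc > 0)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  report <- list(thresholds = list(alpha = alpha, lfc_min = lfcMin,
                                   high_expr = highThreshold,
                                   cut_fraction = cutFraction,
                                   support_lfc = supportLfc))
  elapsed <- list()
  tick <- function() proc.time()[["elapsed"]]

  ## stage 1: inputs ------------------------------------------------------
  t <- tick()
  if (!is.null(simConfig)) {
    validObject(simConfig)
    exp <- simulateCounts(simConfig)
    truth <- truthTable(exp)
    ## per-stage RNG substream: annotations use seed + 1
    fams <- setdiff(.FAMILIES, "none")
    nRec <- simConfig@nReceptorsPerFamily
    recIdx <- seq_len(min(length(fams) * nRec, nrow(exp)))
    ann <- simulateAnnotations(
      setNames(rep(nRec, length(fams)), fams),
      seed = simConfig@seed + 1L, ruleset = ruleset,
      transcriptIds = rownames(exp)[recIdx])
    ## record planted families in the truth table
    truth$receptor_family[match(ann$truth$transcript_id,
                                truth$gene_id)] <- ann$truth$family
    counts <- countsMatrix(exp)
    lengths <- geneLengths(exp)
    design <- designTable(exp)
    immuneFlags <- setNames(truth$is_immune, truth$gene_id)
    domains <- ann$domains; flags <- ann$flags
    report$simulation <- list(seed = simConfig@seed,
                              n_genes = nrow(exp),
                              n_samples = ncol(exp))
    .writeTSV(truth, file.path(outdir, "truth.tsv"))
  } else {
    chk <- validateInputs(inputPaths)
    if (length(chk$warnings)) lapply(chk$warnings, warning, call. = FALSE)
    counts <- readCountsMatrix(inputPaths$counts)
    lt <- read.delim(inputPaths$lengths, stringsAsFactors = FALSE)
    lengths <- setNames(as.numeric(lt[[2]]), lt[[1]])
    design <- read.delim(inputPaths$design, stringsAsFactors = FALSE)
    domains <- if (!is.null(inputPaths$domains))
      readDomainTable(inputPaths$domains) else NULL
    flags <- if (!is.null(inputPaths$flags))
      readFlagsTable(inputPaths$flags) else NULL
    immuneFlags <- if (!is.null(inputPaths$immune_flags)) {
      it <- read.delim(inputPaths$immune_flags, stringsAsFactors = FALSE)
      setNames(as.logical(it[[2]]), it[[1]])
    } else NULL
    truth <- NULL
  }
  .writeMatrixTSV(counts, file.path(outdir, "counts.tsv"))
  .writeTSV(design, file.path(outdir, "design.tsv"))
  .writeTSV(data.frame(gene_id = names(lengths), length = lengths),
            file.path(outdir, "gene_lengths.tsv"))
  report$n_genes <- nrow(counts)
  report$n_samples <- ncol(counts)
  elapsed$inputs <- tick() - t

  ## stage 2: PRR screen --------------------------------------------------
  t <- tick()
  if (!is.null(domains)) {
    scr <- screenTranscriptome(domains, flags, ruleset)
    .writeTSV(scr$calls, file.path(outdir, "receptor_calls.tsv"))
    report$receptor_tally <- as.list(scr$tally)
  } else scr <- NULL
  elapsed$screen <- tick() - t

  ## stage 3: normalization ----------------------------------------------
  t <- tick()
  norm <- tmmNormalizedTPM(counts, lengths)
  .writeMatrixTSV(round(norm$expr, 6), file.path(outdir, "tmm_tpm.tsv"))
  .writeTSV(data.frame(sample_id = colnames(counts),
                       library_size = norm$lib_size,
                       tmm_factor = norm$factors),
            file.path(outdir, "tmm_factors.tsv"))
  elapsed$normalize <- tick() - t

  ## stage 4: layers + individuality -------------------------------------
  t <- tick()
  layers <- callLayers(counts, norm$expr, highThreshold)
  .writeTSV(layers, file.path(outdir, "layers.tsv"))
  summ <- layerSummary(layers)
  report$layer_fractions <- list(
    over_expressed = as.list(summ$frac_expressed),
    over_all = as.list(summ$frac_all))
  if (!is.null(immuneFlags) &&
      any(layers$layer == "constitutive")) {
    imm <- tryCatch(immuneMedianRatio(norm$expr, layers, immuneFlags),
                    error = function(e) NULL)
    if (!is.null(imm))
      report$immune_median <- imm[c("ratio", "median_immune",
                                    "median_other")]
  }
  isGenes <- layers$gene_id[layers$layer == "individual_specific"]
  if (length(isGenes) >= 2) {
    seedPerm <- if (!is.null(simConfig)) simConfig@seed + 2L else 2L
    ind <- individualityAnalysis(presenceMatrix(counts), design,
                                 geneSubset = isGenes,
                                 nPermutations = nPermutations,
                                 seed = seedPerm)
    report$individuality <- list(pairing_score = ind$pairing_score,
                                 p_value = ind$p_value,
                                 n_permutations = ind$n_permutations)
    writeNewick(ind$tree, file.path(outdir, "individuality_tree.nwk"))
  }
  elapsed$layers <- tick() - t

  ## stage 5: differential expression ------------------------------------
  t <- tick()
  de <- list()
  for (tp in unique(design$timepoint)) {
    res <- testContrast(counts, design, tp, normFactors = norm$factors,
                        alpha = alpha, lfcMin = lfcMin)
    de[[tp]] <- res
    .writeTSV(res, file.path(outdir, sprintf("de_%s.tsv", tp)))
  }
  report$deg_counts <- lapply(de, function(res)
    list(up = sum(res$direction == "up"),
         down = sum(res$direction == "down"),
         total = sum(res$significant)))
  if (length(de) == 2) {
    ov <- timepointOverlap(de[[1]], de[[2]])
    report$overlap <- ov[c("shared_up", "shared_down", "n_shared")]
    report$overlap$n_conflicts <- length(ov$conflicts)
  }
  elapsed$detest <- tick() - t

  ## stage 6: consistent / variable partition ----------------------------
  t <- tick()
  report$partition <- list()
  for (tp in names(de)) {
    res <- de[[tp]]
    degIds <- res$gene_id[res$significant]
    if (length(degIds) < 2) next
    sel <- design[design$timepoint == tp, ]
    lpsS <- sel$sample_id[sel$treatment == "LPS"]
    ctlS <- sel$sample_id[sel$treatment == "control"]
    cl <- clusterDEGs(norm$expr, degIds, samples = sel$sample_id,
                      cutFraction = cutFraction)
    sup <- replicateSupport(norm$expr, cl$gene_id, lpsS, ctlS,
                            res$direction[match(cl$gene_id, res$gene_id)],
                            supportLfc = supportLfc)
    part <- labelPartition(cl, sup, nReps = length(lpsS))
    .writeTSV(part$genes, file.path(outdir,
                                    sprintf("partition_%s.tsv", tp)))
    report$partition[[tp]] <- list(
      n_degs = length(degIds),
      n_clusters = nrow(part$clusters),
      fraction_consistent = part$fraction_consistent)
  }
  elapsed$partition <- tick() - t

  ## report ---------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "report.json"))
  report$digests <- setNames(
    lapply(files, function(f) .md5(file.path(outdir, f))), files)
  report$elapsed <- lapply(elapsed, round, 3)
  report$elapsed$total <- round(tick() - t0, 3)
  jsonlite::write_json(report[setdiff(names(report), "elapsed")],
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(c(report, list(outdir = outdir)),
                      class = "immuneLayersReport"))
}

#' @export
print.immuneLayersReport <- function(x, ...) {
  cat("immuneLayers pipeline run —", x$n_genes, "genes x", x$n_samples,
      "samples\n")
  fe <- x$layer_fractions$over_expressed
  cat(sprintf("  layers (expressed genes): constitutive %.1f%%, individual-specific %.1f%%\n",
              100 * fe$constitutive, 100 * fe$individual_specific))
  if (!is.null(x$receptor_tally)) {
    tl <- x$receptor_tally
    cat("  PRR tally:", paste(sprintf("%s=%s", names(tl), unlist(tl)),
                              collapse = " "), "\n")
  }
  if (!is.null(x$immune_median))
    cat(sprintf("  constitutive immune vs other median ratio: %.3f\n",
                x$immune_median$ratio))
  for (tp in names(x$deg_counts)) {
    dc <- x$deg_counts[[tp]]
    pc <- x$partition[[tp]]
    cat(sprintf("  %s: %d DEGs (%d up / %d down)%s\n", tp, dc$total,
                dc$up, dc$down,
                if (!is.null(pc)) sprintf(", %.0f%% consistent",
                                          100 * pc$fraction_consistent)
                else ""))
  }
  if (!is.null(x$overlap))
    cat(sprintf("  timepoint overlap: up %.2f, down %.2f, %d conflicts\n",
                x$overlap$shared_up, x$overlap$shared_down,
                x$overlap$n_conflicts))
  if (!is.null(x$individuality))
    cat(sprintf("  individuality: pairing score %.2f, p = %.4g\n",
                x$individuality$pairing_score, x$individuality$p_value))
  cat("  outputs:", x$outdir, "\n")
  invisible(x)
}

#' Write an hclust tree as Newick
#' @param tree an \code{hclust} object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
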
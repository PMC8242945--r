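#' Pfam domain-architecture rules for PRR family classification
#'
#' Encodes the accession sets behind each pattern-recognition-receptor
#' family call and the precedence used to resolve multi-family
#' architectures. All accession slots are overridable so the screen can be
#' retuned to other Pfam releases or taxa.
#'
#' @slot tirAcc TIR domain accession (PF01582).
#' @slot igAcc immunoglobulin-like accession (PF00047).
#' @slot nachtAcc NACHT accession (PF05729).
#' @slot lrrAcc leucine-rich-repeat accession (PF13516).
#' @slot gpsAcc GPCR proteolytic site accession (PF01825).
#' @slot ctldAcc C-type lectin accession (PF00059).
#' @slot srcrAcc scavenger-receptor cysteine-rich accessions
#'   (PF00530, PF15494).
#' @slot tm7Acc accessions accepted as evidence of a seven-transmembrane
#'   (7TM) region; no single accession defines "7TM", so a small GPCR
#'   family set is used and can be replaced.
#' @slot evalueMax domain hits with evalue above this are ignored.
#' @slot tlrRequiresTM logical; whether the complete TLR-like call requires
#'   a predicted transmembrane segment (relaxable).
#' @slot precedence character vector; first satisfied family wins.
#' @export
setClass("ReceptorRuleset",
  representation(
    tirAcc = "character", igAcc = "character", nachtAcc = "character",
    lrrAcc = "character", gpsAcc = "character", ctldAcc = "character",
    srcrAcc = "character", tm7Acc = "character",
    evalueMax = "numeric", tlrRequiresTM = "logical",
    precedence = "character"))

setValidity("ReceptorRuleset", function(object) {
  msg <- character()
  if (object@evalueMax <= 0) msg <- c(msg, "evalueMax must be positive")
  fams <- setdiff(.FAMILIES, "none")
  if (!setequal(object@precedence, fams))
    msg <- c(msg, paste("precedence must be a permutation of:",
                        paste(fams, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Default PRR classification ruleset
#'
#' TLR_like = TIR + >=1 Ig-like + transmembrane segment; TIR_only = TIR
#' without the full TLR architecture; NLR_bona_fide = NACHT + >=1 LRR;
#' NACHT_only = NACHT without LRR; GPCR_GPS_7TM = 7TM + GPS motif;
#' GPCR_7TM = 7TM alone; SRCR = PF00530 or PF15494; CTLD = PF00059.
#' Precedence: TLR_like > TIR_only > NLR_bona_fide > NACHT_only >
#' GPCR_GPS_7TM > GPCR_7TM > SRCR > CTLD.
#'
#' @param evalueMax e-value cutoff applied to hits before rule evaluation.
#' @param tm7Acc accession set accepted as 7TM evidence.
#' @param tlrRequiresTM require a TM segment for the TLR_like call.
#' @param precedence family resolution order.
#' @return a \linkS4class{ReceptorRuleset}.
#' @examples
#' defaultRuleset()
#' @export
defaultRuleset <- function(evalueMax = 1e-5,
                           tm7Acc = c("PF00001", "PF00002", "PF00003",
                                      "PF10320", "PF10328"),
                           tlrRequiresTM = TRUE,
                           precedence = c("TLR_like", "TIR_only",
                                          "NLR_bona_fide", "NACHT_only",
                                          "GPCR_GPS_7TM", "GPCR_7TM",
                                          "SRCR", "CTLD")) {
  new("ReceptorRuleset",
      tirAcc = "PF01582", igAcc = "PF00047", nachtAcc = "PF05729",
      lrrAcc = "PF13516", gpsAcc = "PF01825", ctldAcc = "PF00059",
      srcrAcc = c("PF00530", "PF15494"), tm7Acc = tm7Acc,
      evalueMax = evalueMax, tlrRequiresTM = tlrRequiresTM,
      precedence = precedence)
}

setMethod("show", "ReceptorRuleset", function(object) {
  cat("ReceptorRuleset (Pfam domain-architecture rules)\n")
  cat("  precedence:", paste(object@precedence, collapse = " > "), "\n")
  cat("  7TM evidence:", paste(object@tm7Acc, collapse = ", "), "\n")
  cat(sprintf("  e-value cutoff: %g; TLR_like requires TM: %s\n",
              object@evalueMax, object@tlrRequiresTM))
})

.checkHits <- function(hits) {
  if (nrow(hits) == 0) return(invisible(TRUE))
  need <- c("accession", "start", "end")
  if (!all(need %in% names(hits)))
    stop("domain hits need columns accession, start, end")
  if (any(!is.finite(hits$start)) || any(!is.finite(hits$end)) ||
      any(hits$start < 1) || any(hits$end < hits$start))
    stop("malformed domain coordinates (need 1 <= start <= end)")
  invisible(TRUE)
}

## Family satisfaction flags from a filtered accession set; used by
## classifyReceptor via precedence (rules after the first match reduce to
## presence tests because the composite forms rank higher).
.familyFlags <- function(accs, hasTM, rs) {
  tir <- rs@tirAcc %in% accs
  ig <- rs@igAcc %in% accs
  nacht <- rs@nachtAcc %in% accs
  lrr <- rs@lrrAcc %in% accs
  tm7 <- any(rs@tm7Acc %in% accs)
  gps <- rs@gpsAcc %in% accs
  c(TLR_like = tir && ig && (hasTM || !rs@tlrRequiresTM),
    TIR_only = tir,
    NLR_bona_fide = nacht && lrr,
    NACHT_only = nacht,
    GPCR_GPS_7TM = tm7 && gps,
    GPCR_7TM = tm7,
    SRCR = any(rs@srcrAcc %in% accs),
    CTLD = rs@ctldAcc %in% accs)
}

.familyAccessions <- function(family, rs) {
  switch(family,
    TLR_like = c(rs@tirAcc, rs@igAcc),
    TIR_only = rs@tirAcc,
    NLR_bona_fide = c(rs@nachtAcc, rs@lrrAcc),
    NACHT_only = rs@nachtAcc,
    GPCR_GPS_7TM = c(rs@tm7Acc, rs@gpsAcc),
    GPCR_7TM = rs@tm7Acc,
    SRCR = rs@srcrAcc,
    CTLD = rs@ctldAcc,
    character())
}

#' Classify one transcript into a PRR family
#'
#' Applies the domain-architecture rules of a
#' \linkS4class{ReceptorRuleset} to the Pfam hits of a single transcript.
#' Hits above the e-value cutoff are dropped first; unknown accessions are
#' ignored. The first satisfied family in the ruleset precedence is
#' returned; localization is \code{membrane_bound} iff a transmembrane
#' segment was predicted.
#'
#' @param hits data.frame of domain hits for one transcript (columns
#'   accession, start, end, optionally name and evalue).
#' @param hasTM logical, predicted transmembrane segment.
#' @param hasSignal logical, predicted signal peptide (carried through).
#' @param ruleset a \linkS4class{ReceptorRuleset}.
#' @return list with \code{family}, \code{localization} and
#'   \code{matched_accessions}.
#' @examples
#' hits <- data.frame(accession = c("PF01582", "PF00047", "PF00047"),
#'                    start = c(10, 220, 320), end = c(150, 300, 400))
#' classifyReceptor(hits, hasTM = TRUE)$family  # "TLR_like"
#' @export
classifyReceptor <- function(hits, hasTM = FALSE, hasSignal = FALSE,
                             ruleset = defaultRuleset()) {
  stopifnot(is(ruleset, "ReceptorRuleset"))
  if (is.null(hits)) hits <- data.frame(accession = character(),
                                        start = numeric(), end = numeric())
  .checkHits(hits)
  if ("evalue" %in% names(hits))
    hits <- hits[is.finite(hits$evalue) & hits$evalue <= ruleset@evalueMax,
                 , drop = FALSE]
  accs <- unique(hits$accession)
  flags <- .familyFlags(accs, isTRUE(hasTM), ruleset)
  sat <- ruleset@precedence[flags[ruleset@precedence]]
  family <- if (length(sat)) sat[[1]] else "none"
  list(family = family,
       localization = if (isTRUE(hasTM)) "membrane_bound" else "non_membrane",
       matched_accessions =
         intersect(accs, .familyAccessions(family, ruleset)))
}

#' Screen a transcriptome for PRR families
#'
#' Runs \code{\link{classifyReceptor}} over every transcript of a domain
#' annotation table and tallies the families. Duplicate
#' (transcript, accession, start) rows are removed with a warning; output
#' is sorted by transcript id and therefore invariant to row order.
#'
#' @param domains data.frame with columns transcript_id, accession, name,
#'   start, end, evalue (name/evalue optional).
#' @param flags data.frame with columns transcript_id, has_tm, has_signal;
#'   transcripts absent from it are treated as lacking both.
#' @param ruleset a \linkS4class{ReceptorRuleset}.
#' @return list with \code{calls} (data.frame: transcript_id, family,
#'   localization) and \code{tally} (named integer over families != none,
#'   plus a \code{none} count).
#' @export
screenTranscriptome <- function(domains, flags = NULL,
                                ruleset = defaultRuleset()) {
  stopifnot(is.data.frame(domains), "transcript_id" %in% names(domains))
  .checkHits(domains)
  key <- paste(domains$transcript_id, domains$accession, domains$start,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate (transcript, accession, start) rows removed")
    domains <- domains[!duplicated(key), , drop = FALSE]
  }
  ids <- sort(unique(c(domains$transcript_id,
                       if (!is.null(flags)) flags$transcript_id)))
  tm <- sig <- setNames(rep(FALSE, length(ids)), ids)
  if (!is.null(flags)) {
    i <- match(flags$transcript_id, ids)
    tm[i] <- as.logical(flags$has_tm)
    if ("has_signal" %in% names(flags)) sig[i] <- as.logical(flags$has_signal)
  }
  byTx <- split(domains[, setdiff(names(domains), "transcript_id"),
                        drop = FALSE],
                factor(domains$transcript_id, levels = ids))
  calls <- do.call(rbind, lapply(ids, function(id) {
    cl <- classifyReceptor(byTx[[id]], hasTM = tm[[id]],
                           hasSignal = sig[[id]], ruleset = ruleset)
    data.frame(transcript_id = id, family = cl$family,
               localization = cl$localization)
  }))
  fams <- setdiff(.FAMILIES, "none")
  tally <- setNames(integer(length(fams)), fams)
  tt <- table(calls$family)
  tally[names(tt)[names(tt) %in% fams]] <- tt[names(tt) %in% fams]
  list(calls = calls,
       tally = c(tally, none = sum(calls$family == "none")))
}

#' Read the 6-column tab-separated domain-hit table
#'
#' Columns: transcript_id, accession, name, start, end, evalue.
#' @param path file path.
#' @return data.frame of domain hits.
#' @export
readDomainTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "accession", "name", "start", "end", "evalue")
  if (!all(need %in% names(d)))
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  d
}

#' Read the per-transcript localization flags table
#' @param path tab-separated file with transcript_id, has_tm, has_signal.
#' @return data.frame of logical flags.
#' @export
readFlagsTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "has_tm") %in% names(d)))
    stop("flags table needs columns transcript_id and has_tm")
  d$has_tm <- as.logical(d$has_tm)
  if ("has_signal" %in% names(d)) d$has_signal <- as.logical(d$has_signal)
  d
}

#' Read HMMER per-domain output (domtblout)
#'
#' Parses the whitespace-delimited per-domain hits table written by
#' \code{hmmscan --domtblout}, keeping target name, query accession,
#' envelope coordinates and the independent e-value, and returns them in
#' the 6-column dialect used by \code{\link{screenTranscriptome}}.
#'
#' @param path domtblout file.
#' @return data.frame with transcript_id, accession, name, start, end,
#'   evalue.
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(transcript_id = character(), accession = character(),
                      name = character(), start = numeric(),
                      end = numeric(), evalue = numeric()))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- vapply(fields, length, 0L) < 23
  if (any(short)) stop("malformed domtblout line(s): fewer than 23 fields")
  get <- function(i) vapply(fields, `[[`, "", i)
  ## domtblout layout: 1 target name, 2 target accession, 4 query name,
  ## 13 independent (i-)E-value, 20-21 envelope from/to
  data.frame(
    transcript_id = get(4),
    accession = sub("\\.\\d+$", "", get(2)),
    name = get(1),
    start = as.numeric(get(20)),
    end = as.numeric(get(21)),
    evalue = as.numeric(get(13)),
    stringsAsFactors = FALSE)
}
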
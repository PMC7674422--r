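## Deterministic marker-filter cascade on precomputed ortholog metrics.
## The filters run in a fixed order; each step's removals are logged in a
## FilterReport data.frame (step, unit, before, removed, after).

.reportRow <- function(step, unit, before, removed) {
  data.frame(step = step, unit = unit, before = before, removed = removed,
             after = before - removed)
}

#' Sequence-level and exon-level ortholog filters
#'
#' Applies, in order: (1) removal of sequences whose similarity bitscore is
#' below \code{relativeBitscoreFraction} of the highest bitscore achieved by
#' any ingroup sequence of the same exon; (2) removal of sequences with
#' dN/dS strictly greater than \code{dndsMax} (a sequence at exactly the
#' threshold is retained); (3) removal of whole exons with more than
#' \code{maxMissing} missing sequences (species without a retained
#' sequence).
#'
#' @param table data.frame with one row per (gene, exon, species) and columns
#'   \code{gene}, \code{exon}, \code{species}, \code{bitscore},
#'   \code{bitscoreThreshold}, \code{dnds}, \code{gc}, \code{present}
#'   (logical), \code{length}, plus optional coordinate columns.
#' @param relativeBitscoreFraction fraction of the best ingroup bitscore a
#'   sequence must reach (default 0.9).
#' @param dndsMax maximum tolerated dN/dS (default 0.25; rule is "> max").
#' @param maxMissing maximum missing sequences per exon (default 10).
#' @param nSpecies total species expected per exon; default the number of
#'   distinct species in \code{table}.
#' @return list with \code{table} (filtered rows) and \code{report} (a
#'   FilterReport data.frame).
#' @export
applySequenceFilters <- function(table, relativeBitscoreFraction = 0.9,
                                 dndsMax = 0.25, maxMissing = 10,
                                 nSpecies = NULL) {
  req <- c("gene", "exon", "species", "bitscore", "bitscoreThreshold",
           "dnds", "present")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  if (!nrow(table)) stop("schema error: empty table")
  stopifnot(relativeBitscoreFraction > 0, dndsMax > 0)
  if (is.null(nSpecies)) nSpecies <- length(unique(table$species))

  tab <- table[table$present & table$bitscore >= table$bitscoreThreshold, ,
               drop = FALSE]
  exonKey <- function(x) paste(x$gene, x$exon, sep = "\r")

  # (1) relative bitscore within each exon's candidate set
  best <- tapply(tab$bitscore, exonKey(tab), max)
  keep <- tab$bitscore >= relativeBitscoreFraction * best[exonKey(tab)]
  r1 <- .reportRow("relative_bitscore", "sequences", nrow(tab), sum(!keep))
  tab <- tab[keep, , drop = FALSE]

  # (2) dN/dS; strictly greater than the threshold is removed
  keep <- !(tab$dnds > dndsMax)
  r2 <- .reportRow("dnds", "sequences", nrow(tab), sum(!keep))
  tab <- tab[keep, , drop = FALSE]

  # (3) exons with too many missing species
  cnt <- tapply(tab$species, exonKey(tab), function(x) length(unique(x)))
  dropExon <- names(cnt)[nSpecies - cnt > maxMissing]
  keep <- !(exonKey(tab) %in% dropExon)
  r3 <- .reportRow("missing_sequences", "exons", length(cnt),
                   length(dropExon))
  tab <- tab[keep, , drop = FALSE]

  list(table = tab, report = rbind(r1, r2, r3))
}

#' Alignment-level and gene-structure filters
#'
#' Applies, in order: (4) masking of whole codons in which any site has more
#' than \code{missingSiteMax} missing data or whose smoothed entropy-like
#' score exceeds \code{entropyMax} (masking removes codon triplets only, so
#' alignment length stays divisible by 3); (5) removal of alignments shorter
#' than \code{minLength} after masking; (6) removal of alignments whose
#' among-sequence SD in GC content exceeds \code{gcSdMax}; (7) removal of
#' all exons of genes with fewer than \code{minExons} surviving exons or
#' whose exons span more than \code{maxExonSpan} bp on the reference genome
#' (0-based half-open coordinates, span = max(end) - min(start)); optionally
#' (8) removal of exons flagged discordant and re-application of the
#' \code{minExons} rule; (9) removal of manually excluded genes.
#'
#' @param alignments named list of equal-length character vectors (or
#'   DNAStringSet objects), one per exon, names "gene:exon".
#' @param exonInfo data.frame with columns \code{gene}, \code{exon},
#'   \code{start}, \code{end} (reference coordinates) and optionally
#'   \code{concordant} (logical).
#' @param entropyScores named list of per-codon entropy-like scores aligned
#'   with \code{alignments} (computed externally).
#' @param minLength minimum post-masking alignment length in bp.
#' @param missingSiteMax maximum fraction of missing data per site.
#' @param entropyMax maximum smoothed entropy-like score per codon.
#' @param gcSdMax maximum among-sequence SD in GC content.
#' @param minExons minimum surviving exons per gene.
#' @param maxExonSpan maximum reference span of a gene's exons (bp).
#' @param manualExclude character vector of gene ids to drop (visual check).
#' @return list with \code{alignments} (masked, surviving), \code{mask}
#'   (list of logical codon-keep vectors) and \code{report}.
#' @export
applyAlignmentFilters <- function(alignments, exonInfo, entropyScores = NULL,
                                  minLength = 150, missingSiteMax = 0.20,
                                  entropyMax = 0.5, gcSdMax = 0.04,
                                  minExons = 3, maxExonSpan = 1e5,
                                  manualExclude = character(0)) {
  req <- c("gene", "exon", "start", "end")
  miss <- setdiff(req, names(exonInfo))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  alnChar <- lapply(alignments, function(a)
    if (is(a, "DNAStringSet")) as.character(a) else a)
  key <- paste(exonInfo$gene, exonInfo$exon, sep = ":")
  if (!all(names(alnChar) %in% key))
    stop("schema error: alignments lack matching exonInfo rows")

  # (4) codon masking
  nCodonsMasked <- 0L
  masks <- vector("list", length(alnChar))
  names(masks) <- names(alnChar)
  for (nm in names(alnChar)) {
    a <- alnChar[[nm]]
    L <- unique(nchar(a))
    if (length(L) != 1L) stop("frame error: unequal sequence lengths in ", nm)
    if (L %% 3 != 0) stop("frame error: alignment length of ", nm,
                          " not divisible by 3")
    mat <- do.call(rbind, strsplit(toupper(a), "", fixed = TRUE))
    missFrac <- colMeans(mat == "N" | mat == "-" | mat == "?")
    nCod <- L %/% 3
    codBad <- vapply(seq_len(nCod), function(i) {
      cols <- (3L * (i - 1L) + 1L):(3L * i)
      any(missFrac[cols] > missingSiteMax)
    }, logical(1L))
    if (!is.null(entropyScores) && !is.null(entropyScores[[nm]])) {
      ent <- entropyScores[[nm]]
      if (length(ent) != nCod)
        stop("frame error: entropy scores of ", nm,
             " must be one value per codon")
      codBad <- codBad | ent > entropyMax
    }
    nCodonsMasked <- nCodonsMasked + sum(codBad)
    masks[[nm]] <- !codBad
    keepCols <- rep(!codBad, each = 3L)
    alnChar[[nm]] <- apply(mat[, keepCols, drop = FALSE], 1L, paste,
                           collapse = "")
    names(alnChar[[nm]]) <- names(a)
  }
  totCod <- sum(vapply(masks, length, integer(1L)))
  r4 <- .reportRow("codon_mask", "codons", totCod, nCodonsMasked)

  # (5) minimum alignment length after masking
  len <- vapply(alnChar, function(a) unique(nchar(a))[1L], numeric(1L))
  keep <- len >= minLength
  r5 <- .reportRow("min_length", "alignments", length(alnChar), sum(!keep))
  alnChar <- alnChar[keep]

  # (6) among-sequence GC-content SD
  gcSd <- vapply(alnChar, function(a) {
    chars <- strsplit(toupper(a), "", fixed = TRUE)
    gc <- vapply(chars, function(x) {
      known <- x %in% c("A", "C", "G", "T")
      if (!any(known)) return(NA_real_)
      sum(x %in% c("G", "C")) / sum(known)
    }, numeric(1L))
    stats::sd(gc, na.rm = TRUE)
  }, numeric(1L))
  keep <- is.na(gcSd) | gcSd <= gcSdMax
  r6 <- .reportRow("gc_sd", "alignments", length(alnChar), sum(!keep))
  alnChar <- alnChar[keep]

  # (7) gene structure: exon count and reference span
  info <- exonInfo[key %in% names(alnChar), , drop = FALSE]
  geneOK <- function(info) {
    cnt <- table(info$gene)
    span <- tapply(info$end, info$gene, max) -
      tapply(info$start, info$gene, min)
    names(cnt)[cnt >= minExons & span[names(cnt)] <= maxExonSpan]
  }
  good <- geneOK(info)
  keep <- info$gene %in% good
  r7 <- .reportRow("gene_structure", "alignments", nrow(info), sum(!keep))
  info <- info[keep, , drop = FALSE]
  alnChar <- alnChar[paste(info$gene, info$exon, sep = ":")]

  report <- rbind(r4, r5, r6, r7)

  # (8) concordance flags (computed externally), then exon count again
  if ("concordant" %in% names(exonInfo)) {
    conc <- exonInfo$concordant[match(paste(info$gene, info$exon, sep = ":"),
                                      key)]
    keep <- conc & info$gene %in% geneOK(info[conc, , drop = FALSE])
    report <- rbind(report, .reportRow("concordance", "alignments",
                                       nrow(info), sum(!keep)))
    info <- info[keep, , drop = FALSE]
    alnChar <- alnChar[paste(info$gene, info$exon, sep = ":")]
  }

  # (9) manual exclusion list
  if (length(manualExclude)) {
    keep <- !(info$gene %in% manualExclude)
    report <- rbind(report, .reportRow("manual_exclusion", "alignments",
                                       nrow(info), sum(!keep)))
    info <- info[keep, , drop = FALSE]
    alnChar <- alnChar[paste(info$gene, info$exon, sep = ":")]
  }

  list(alignments = alnChar, mask = masks, report = report)
}

#' Select the permissive and strict gene sets from per-gene clock metrics
#'
#' The permissive set keeps genes with a minimum ESS above 100, a
#' substitution rate below 1.6e-9 per year and site, and a coefficient of
#' among-branch rate variation below 0.7; the strict set tightens these to
#' 200, 1.4e-9 and 0.6 and is always a subset of the permissive set.
#'
#' @param metrics data.frame with columns \code{gene}, \code{minESS},
#'   \code{rate}, \code{rateCV}.
#' @return list with character vectors \code{permissive} and \code{strict}.
#' @examples
#' m <- data.frame(gene = "g1", minESS = 150, rate = 1.5e-9, rateCV = 0.65)
#' selectGeneSets(m)
#' @export
selectGeneSets <- function(metrics) {
  req <- c("gene", "minESS", "rate", "rateCV")
  miss <- setdiff(req, names(metrics))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  permissive <- metrics$gene[metrics$minESS > 100 & metrics$rate < 1.6e-9 &
                               metrics$rateCV < 0.7]
  strict <- metrics$gene[metrics$minESS > 200 & metrics$rate < 1.4e-9 &
                           metrics$rateCV < 0.6]
  list(permissive = as.character(permissive), strict = as.character(strict))
}
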
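## Readers/writers. Trees go through ape, constraint files through yaml /
## jsonlite. Tabular outputs carry a provenance header in '#' comment lines:
## tool version, seed, and a hash of the generating configuration.

# polynomial rolling hash of a deparsed object, hex string
.configHash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenanceHeader <- function(seed = NA, config = NULL) {
  c(sprintf("# fossilcal %s",
            as.character(utils::packageVersion("fossilcal"))),
    sprintf("# seed: %s", seed),
    sprintf("# config: %s", .configHash(config)))
}

#' Read a rooted time tree from Newick or NEXUS
#'
#' Edge lengths are interpreted as durations in Myr; the tree must be rooted,
#' strictly binary and ultrametric. Square-bracket comments in Newick are
#' ignored; node labels are allowed.
#'
#' @param path file path.
#' @param format "newick" or "nexus"; default guessed from the extension.
#' @return a \code{\linkS4class{TimeTree}}.
#' @export
readTimeTree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "newick"
  if (format == "newick") {
    txt <- paste(readLines(path, warn = FALSE), collapse = "")
    txt <- gsub("\\[[^]]*\\]", "", txt)  # strip bracket comments
    depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                           ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
    if (any(depth < 0L))
      stop("parse error at byte ", which(depth < 0L)[1L],
           ": unbalanced parenthesis")
    if (depth[length(depth)] != 0L)
      stop("parse error at byte ", nchar(txt),
           ": unbalanced parenthesis")
    phy <- ape::read.tree(text = txt)
  } else {
    phy <- ape::read.nexus(path)
  }
  if (is.null(phy)) stop("parse error: could not read a tree from ", path)
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  timeTree(phy)
}

#' Write a TimeTree to Newick or NEXUS
#'
#' Branch lengths are written as Myr durations with enough digits that a
#' write-read round trip preserves node ages to 1e-9 Ma.
#'
#' @param tree a \code{TimeTree}.
#' @param path output path.
#' @param format "newick" or "nexus".
#' @export
writeTimeTree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(tree, "TimeTree"))
  phy <- tree@phylo
  if (format == "newick") {
    ape::write.tree(phy, file = path, digits = 15)
  } else {
    # write.nexus would round branch lengths to 10 significant digits;
    # embed a full-precision newick string instead
    writeLines(c("#NEXUS", "BEGIN TREES;",
                 paste0("  TREE tree1 = ",
                        ape::write.tree(phy, digits = 15)),
                 "END;"), path)
  }
  invisible(path)
}

#' Read clade calibration constraints from YAML or JSON
#'
#' The file holds a list of clades, each with a label, a tip set and one or
#' two fossils (\code{name}, \code{age_min}, \code{age_max}, optional
#' \code{weight}), plus an optional \code{bd} block with point-or-range
#' values for \code{net_diversification}, \code{turnover} and
#' \code{sampling_rate}. A single fossil defaults to weight 1; two-fossil
#' weights must sum to 1; more than two fossils are rejected (the mixture
#' model is explicitly two-fossil).
#'
#' @param path file path (.yaml/.yml or .json).
#' @return list with \code{constraints} (list of
#'   \code{\link{CladeConstraint}}) and \code{bd} (\code{\link{BDParams}} or
#'   NULL).
#' @export
readConstraints <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  clades <- raw$clades
  if (is.null(clades)) stop("validation error: no 'clades' block in ", path)
  constraints <- lapply(clades, function(cl) {
    if (is.null(cl$label) || is.null(cl$tips))
      stop("validation error: each clade needs a label and tips")
    fos <- cl$fossils
    if (length(fos) > 2L)
      stop("validation error: clade '", cl$label, "' lists ", length(fos),
           " fossils; the mixture model supports at most two candidate ",
           "first records")
    if (length(fos) < 1L)
      stop("validation error: clade '", cl$label, "' lists no fossils")
    w <- vapply(fos, function(f)
      if (is.null(f$weight)) NA_real_ else as.numeric(f$weight),
      numeric(1L))
    if (length(fos) == 1L) {
      if (is.na(w)) w <- 1  # single fossil defaults to certainty
    } else {
      if (anyNA(w)) stop("validation error: clade '", cl$label,
                         "' has two fossils but missing weights")
      if (abs(sum(w) - 1) > 1e-9)
        stop("validation error: fossil weights of clade '", cl$label,
             "' sum to ", sum(w), ", not 1")
    }
    fr <- lapply(seq_along(fos), function(i) {
      f <- fos[[i]]
      amin <- as.numeric(f$age_min)
      amax <- as.numeric(if (is.null(f$age_max)) f$age_min else f$age_max)
      if (amin > amax)
        stop("validation error: fossil '", f$name, "' in clade '",
             cl$label, "' has age_min > age_max")
      FossilRecord(f$name, amin, amax, weight = w[i])
    })
    CladeConstraint(cl$label, unlist(cl$tips), fr)
  })
  bd <- NULL
  if (!is.null(raw$bd))
    bd <- BDParams(unlist(raw$bd$net_diversification),
                   unlist(raw$bd$turnover), unlist(raw$bd$sampling_rate))
  list(constraints = constraints, bd = bd)
}

#' Write or read a calibration density as two-column TSV
#'
#' @param density a \code{CalibrationDensity}.
#' @param path file path.
#' @param seed,config recorded in the provenance header.
#' @return \code{readDensityTSV} returns a \code{CalibrationDensity}
#'   rebuilt from the table.
#' @export
writeDensityTSV <- function(density, path, seed = NA, config = NULL) {
  stopifnot(is(density, "CalibrationDensity"))
  writeLines(.provenanceHeader(seed, config), path)
  suppressWarnings(utils::write.table(
    densityTable(density), path, sep = "\t", row.names = FALSE,
    quote = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname writeDensityTSV
#' @export
readDensityTSV <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#")
  .newCalibrationDensity(tab$age, tab$density)
}

#' Write or read an MCMC trace as tab-separated text
#'
#' @param trace an \code{MCMCTrace}.
#' @param path file path.
#' @return \code{readTrace} returns an \code{MCMCTrace} (meta reduced to
#'   what the header records).
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "MCMCTrace"))
  hdr <- c(.provenanceHeader(trace@seed, trace@meta$topology),
           sprintf("# thinning: %d", as.integer(trace@thinning)),
           sprintf("# burninFraction: %g", trace@burninFraction))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    trace@samples, path, sep = "\t", row.names = FALSE, quote = FALSE,
    append = TRUE))
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  pick <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(paste0("^# ", key, ": *"), "", m[1L]))
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  new("MCMCTrace", samples = tab, thinning = pick("thinning", 1),
      burninFraction = pick("burninFraction", 0),
      seed = pick("seed", NA_real_), meta = list())
}

#' Write a filter report as TSV
#'
#' @param report FilterReport data.frame from the filter cascade.
#' @param path file path.
#' @export
writeFilterReport <- function(report, path) {
  writeLines(.provenanceHeader(), path)
  suppressWarnings(utils::write.table(
    report, path, sep = "\t", row.names = FALSE, quote = FALSE,
    append = TRUE))
  invisible(path)
}
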
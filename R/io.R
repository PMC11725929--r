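#' Write a TCSPC stack as a multi-page TIFF with a sidecar config
#'
#' Pages are time channels, stored as 16-bit counts. The sidecar is a plain
#' key-value text file (\code{key = value} per line) carrying
#' \code{n_channels}, \code{time_window_ns}, \code{condition} and
#' \code{imposed_pO2}.
#'
#' @param image a [TCSPCImage-class].
#' @param tiffFile output TIFF path.
#' @param configFile output sidecar path; default \code{tiffFile} with a
#'   \code{.cfg} extension.
#' @return invisibly, the two paths.
#' @export
writeTCSPC <- function(image, tiffFile,
                       configFile = sub("\\.tiff?$", ".cfg", tiffFile)) {
  stopifnot(methods::is(image, "TCSPCImage"))
  cnt <- image@counts
  if (max(cnt) > 65535)
    stop("photon counts exceed the 16-bit TIFF range")
  C <- dim(cnt)[3L]
  pages <- lapply(seq_len(C), function(k) cnt[, , k] / 65535)
  tiff::writeTIFF(pages, tiffFile, bits.per.sample = 16L,
                  compression = "none")
  writeLines(c(
    sprintf("n_channels = %d", C),
    sprintf("time_window_ns = %.10g", image@timeWindow),
    sprintf("condition = %s", image@condition),
    sprintf("imposed_pO2 = %s",
            if (is.na(image@imposedPO2)) "NA"
            else sprintf("%.10g", image@imposedPO2))), configFile)
  invisible(c(tiff = tiffFile, config = configFile))
}

#' Read a TCSPC stack written by [writeTCSPC()]
#'
#' @param tiffFile multi-page TIFF path (pages = time channels).
#' @param configFile sidecar config path.
#' @return a [TCSPCImage-class].
#' @export
readTCSPC <- function(tiffFile,
                      configFile = sub("\\.tiff?$", ".cfg", tiffFile)) {
  pages <- tiff::readTIFF(tiffFile, all = TRUE)
  cfg <- readSidecar(configFile)
  C <- as.integer(cfg[["n_channels"]])
  if (length(pages) != C)
    stop("TIFF has ", length(pages), " pages but sidecar declares ",
         C, " channels")
  cube <- array(0, dim = c(dim(pages[[1L]]), C))
  for (k in seq_len(C)) cube[, , k] <- round(pages[[k]] * 65535)
  methods::new("TCSPCImage",
    counts = cube,
    timeWindow = as.numeric(cfg[["time_window_ns"]]),
    condition = cfg[["condition"]],
    imposedPO2 = suppressWarnings(as.numeric(cfg[["imposed_pO2"]])))
}

readSidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)\\s*$", lines))
  out <- vapply(kv, function(m) m[3L], character(1))
  names(out) <- vapply(kv, function(m) m[2L], character(1))
  as.list(out)
}

#' Write / read a qPCR Ct table
#'
#' Tab-delimited text with header columns \code{sample}, \code{target},
#' \code{role}, \code{dilution} and one \code{ct<i>} column per replicate,
#' as produced by [generateCtTable()].
#'
#' @param ctTable data.frame in the documented layout.
#' @param file path.
#' @return \code{writeCtTable}: invisibly the path; \code{readCtTable}: the
#'   data.frame.
#' @export
writeCtTable <- function(ctTable, file) {
  utils::write.table(ctTable, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeCtTable
#' @export
readCtTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Turn one Ct-table row into a [CtRecord-class]
#'
#' @param row a single-row data.frame from [readCtTable()].
#' @param inputFraction input fraction carried onto the record
#'   (default 0.02).
#' @return a [CtRecord-class].
#' @export
ctRecordFromRow <- function(row, inputFraction = 0.02) {
  ctCols <- grep("^ct[0-9]+$", names(row), value = TRUE)
  ctRecord(as.character(row$sample), as.character(row$target),
           as.character(row$role), as.numeric(row[ctCols]),
           dilution = as.numeric(row$dilution),
           inputFraction = inputFraction)
}

#' Write / read a read-interval table
#'
#' Tab-delimited text with header \code{start}, \code{end}, \code{strand}
#' (1-based inclusive coordinates on the circular reference; \code{end} may
#' exceed the genome length for origin-spanning reads).
#'
#' @param reads data.frame as produced by [generateReads()].
#' @param file path.
#' @return \code{writeReadTable}: invisibly the path; \code{readReadTable}:
#'   the data.frame.
#' @export
writeReadTable <- function(reads, file) {
  utils::write.table(reads, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeReadTable
#' @export
readReadTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write a binned signal as bedGraph
#'
#' 0-based half-open intervals over a single circular contig; the final bin
#' is truncated at the genome length.
#'
#' @param signal a [BinnedSignal-class].
#' @param file path.
#' @param chrom contig name (default \code{"chrM"}).
#' @return invisibly, the path.
#' @export
writeBedGraph <- function(signal, file, chrom = "chrM") {
  stopifnot(methods::is(signal, "BinnedSignal"))
  n <- length(signal@values)
  start0 <- (seq_len(n) - 1L) * signal@binSize
  end0 <- pmin(start0 + signal@binSize, signal@genomeLength)
  utils::write.table(
    data.frame(chrom = chrom, start = start0, end = end0,
               value = signal@values),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
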
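#' @title External format readers and writers
#' @description Readers/writers for bedGraph, BED6, narrowPeak, GFF3, FASTA
#'   and the tab-separated feature table, plus paired-end fragment to dyad
#'   conversion. All readers convert to the internal 0-based half-open
#'   convention; GFF3 converts back to 1-based inclusive on write.
#' @name formats_io
NULL

# Read, strip comment/track/browser lines, split on whitespace; returns
# list(fields = list of character vectors, line = original line numbers).
.read_fields <- function(path, ncol, format) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  sp <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(sp)
  if (any(nf != ncol)) {
    bad <- idx[which(nf != ncol)[1L]]
    stop(sprintf("%s parse error at line %d of %s: expected %d fields, found %d",
                 format, bad, path, ncol, nf[which(nf != ncol)[1L]]))
  }
  list(fields = sp, line = idx)
}

.num_field <- function(x, line, path, what, format) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("%s parse error at line %d of %s: non-numeric %s '%s'",
                 format, line[bad], path, what, x[bad]))
  }
  out
}

#' Read a bedGraph file into a SignalTrack
#'
#' @param path path to a 4-column bedGraph file (0-based half-open).
#' @param strand_label strand to attach to the track: `"+"`, `"-"` or `"."`.
#' @param ... further metadata passed to [signal_track()].
#' @return a [signal_track()]; absent positions mean 0. Zero-length intervals
#'   and overlapping records are errors.
#' @export
read_bedgraph <- function(path, strand_label = ".", ...) {
  p <- .read_fields(path, 4L, "bedGraph")
  if (!length(p$fields))
    return(signal_track(NULL, strand = strand_label, ...))
  m <- do.call(rbind, p$fields)
  start <- .num_field(m[, 2], p$line, path, "start", "bedGraph")
  end <- .num_field(m[, 3], p$line, path, "end", "bedGraph")
  value <- .num_field(m[, 4], p$line, path, "value", "bedGraph")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("bedGraph format error at line %d of %s: empty interval [%d, %d)",
                 p$line[bad[1L]], path, as.integer(start[bad[1L]]),
                 as.integer(end[bad[1L]])))
  dt <- data.table(chrom = m[, 1], start = as.integer(start),
                   end = as.integer(end), value = value)
  setorder(dt, chrom, start)
  ov <- dt[, if (.N > 1L) any(start[-1L] < end[-.N]) else FALSE, by = chrom]$V1
  if (any(ov))
    stop(sprintf("bedGraph format error in %s: overlapping records", path))
  signal_track(dt, strand = strand_label, ...)
}

#' Write a SignalTrack as bedGraph
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  fwrite(track$runs, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}

#' Read a BED6 file of long-read alignment spans
#'
#' The score column is carried but ignored by the pipeline. Coordinates are
#' 0-based half-open; the 5' end of a minus-strand span is its last covered
#' base (`end - 1`).
#'
#' @param path path to a 6-column BED file.
#' @return data.table with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  p <- .read_fields(path, 6L, "BED6")
  if (!length(p$fields))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character()))
  m <- do.call(rbind, p$fields)
  start <- as.integer(.num_field(m[, 2], p$line, path, "start", "BED6"))
  end <- as.integer(.num_field(m[, 3], p$line, path, "end", "BED6"))
  if (any(end <= start))
    stop(sprintf("BED6 format error at line %d of %s: empty interval",
                 p$line[which(end <= start)[1L]], path))
  if (!all(m[, 6] %in% c("+", "-", ".")))
    stop(sprintf("BED6 parse error at line %d of %s: bad strand",
                 p$line[which(!m[, 6] %in% c("+", "-", "."))[1L]], path))
  data.table(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = .num_field(m[, 5], p$line, path, "score", "BED6"),
             strand = m[, 6])
}

#' Write long-read spans as BED6
#'
#' @param spans data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed6 <- function(spans, path) {
  dt <- as.data.table(spans)[, .(chrom, start, end, name, score, strand)]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE, scipen = 50L)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' Standard 10-column ENCODE narrowPeak. The summit is stored as an absolute
#' genome position (`start + peak_offset`); an offset of -1 (no summit call)
#' falls back to the interval midpoint. Enrichment (`signalValue`) is on the
#' linear scale.
#'
#' @param path path to the narrowPeak file.
#' @return data.table with the 10 narrowPeak columns plus `summit`.
#' @export
read_narrowpeak <- function(path) {
  p <- .read_fields(path, 10L, "narrowPeak")
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character(), signalValue = numeric(),
                      pValue = numeric(), qValue = numeric(), peak = integer(),
                      summit = integer())
  if (!length(p$fields)) return(empty)
  m <- do.call(rbind, p$fields)
  start <- as.integer(.num_field(m[, 2], p$line, path, "start", "narrowPeak"))
  end <- as.integer(.num_field(m[, 3], p$line, path, "end", "narrowPeak"))
  peak <- as.integer(.num_field(m[, 10], p$line, path, "peak offset", "narrowPeak"))
  summit <- ifelse(peak < 0L, start + (end - start) %/% 2L, start + peak)
  data.table(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = .num_field(m[, 5], p$line, path, "score", "narrowPeak"),
             strand = m[, 6],
             signalValue = .num_field(m[, 7], p$line, path, "signalValue", "narrowPeak"),
             pValue = .num_field(m[, 8], p$line, path, "pValue", "narrowPeak"),
             qValue = .num_field(m[, 9], p$line, path, "qValue", "narrowPeak"),
             peak = peak, summit = as.integer(summit))
}

#' Write peaks as narrowPeak
#'
#' @param peaks data.frame with the 10 standard narrowPeak columns (a `summit`
#'   column, if present, is dropped on write and recomputed on read).
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  dt <- as.data.table(peaks)[, .(chrom, start, end, name, score, strand,
                                 signalValue, pValue, qValue, peak)]
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE, scipen = 50L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `CDS` (or, lacking CDS, `gene`) features and converts the 1-based
#' inclusive GFF3 coordinates to 0-based half-open. Records without a strand
#' are rejected with a warning. The gene identifier is taken from the `ID=`
#' (or `Parent=`) attribute.
#'
#' @param path path to a GFF3 file.
#' @return data.table of gene models: `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_gff3 <- function(path) {
  p <- .read_fields(path, 9L, "GFF3")
  empty <- data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character())
  if (!length(p$fields)) return(empty)
  m <- do.call(rbind, p$fields)
  type <- m[, 3]
  keep <- type %in% if (any(type == "CDS")) "CDS" else "gene"
  if (!any(keep)) return(empty)
  m <- m[keep, , drop = FALSE]; line <- p$line[keep]
  strand <- m[, 7]
  ok <- strand %in% c("+", "-")
  if (any(!ok))
    warning(sprintf("GFF3: %d record(s) without strand rejected (first at line %d)",
                    sum(!ok), line[which(!ok)[1L]]))
  m <- m[ok, , drop = FALSE]; line <- line[ok]
  if (!nrow(m)) return(empty)
  start1 <- .num_field(m[, 4], line, path, "start", "GFF3")
  end1 <- .num_field(m[, 5], line, path, "end", "GFF3")
  id <- sub(";.*$", "", m[, 9])
  id <- sub("^(ID|Parent|gene_id)=", "", id)
  id[m[, 9] == "."] <- NA_character_
  dt <- data.table(gene_id = id, chrom = m[, 1],
                   start = as.integer(start1) - 1L, end = as.integer(end1),
                   strand = m[, 7])
  idx <- which(is.na(dt$gene_id))
  if (length(idx)) dt$gene_id[idx] <- sprintf("feature_%d", idx)
  dt
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open gene models are written as 1-based inclusive
#' `CDS` features, so that read/write round-trips preserve the GFF3
#' coordinates exactly.
#'
#' @param genes data.frame from [read_gff3()] (or the synthetic generator).
#' @param path output path.
#' @param source source tag for column 2.
#' @export
write_gff3 <- function(genes, path, source = "lutiscan") {
  dt <- as.data.table(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     dt$chrom, source, dt$start + 1L, dt$end, dt$strand,
                     dt$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a named character vector, one element per sequence.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(genome)), path, width = 80L)
  invisible(path)
}

#' Write / read the per-gene feature table
#'
#' Tab-separated with a header, one row per gene; missing values are written
#' as empty cells and read back as `NA`. `write_feature_table()` followed by
#' [read_feature_table()] is lossless.
#'
#' @param rows data.frame of per-gene features.
#' @param path file path.
#' @export
write_feature_table <- function(rows, path) {
  fwrite(as.data.table(rows), path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  fread(path, sep = "\t", na.strings = "", header = TRUE)
}

#' Convert paired-end fragment spans to nucleosome dyad counts
#'
#' Keeps fragments whose length falls inside the mononucleosome size
#' selection (130-170 bp by default) and places one dyad at the floor of
#' each fragment midpoint.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open spans).
#' @param min_len,max_len inclusive fragment-length bounds in bp.
#' @param ... metadata passed to [signal_track()].
#' @return an unstranded [signal_track()] of per-base dyad counts.
#' @export
fragments_to_dyads <- function(fragments, min_len = 130L, max_len = 170L, ...) {
  dt <- as.data.table(fragments)
  dt <- dt[(end - start) >= min_len & (end - start) <= max_len]
  if (!nrow(dt)) return(signal_track(NULL, strand = ".", units = "dyads", ...))
  pos <- (dt$start + dt$end) %/% 2L
  positions_to_track(data.table(chrom = dt$chrom, pos = pos, value = 1),
                     strand = ".", units = "dyads", ...)
}
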
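#' Read a FASTA file into a named vector of sequences
#'
#' Sequences are uppercased. Characters outside the {A,C,G,T,N} alphabet are
#' rejected (\code{on_other = "error"}) or replaced by N
#' (\code{on_other = "to_n"}).
#'
#' @param path FASTA file path.
#' @param on_other How to handle non-ACGTN characters.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path, on_other = c("error", "to_n")) {
  on_other <- match.arg(on_other)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (on_other == "error") {
      stop("record '", names(seqs)[bad][1],
           "' contains characters outside {A,C,G,T,N}")
    }
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read BED6 or narrowPeak records
#'
#' @param path Tab-separated file, no header. BED6 needs >= 3 columns
#'   (missing name/score/strand filled with defaults); narrowPeak needs
#'   exactly 10.
#' @param kind "bed6" or "narrowPeak".
#' @return For bed6, an interval data.frame; for narrowPeak, intervals plus
#'   score, signal, pvalue_log, qvalue_log, summit_offset columns.
#' @export
read_bed <- function(path, kind = c("bed6", "narrowPeak")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  nc <- ncol(dt)
  if (kind == "bed6") {
    if (nc < 3L) stop("BED6 file needs >= 3 columns, got ", nc, ": ", path)
  } else {
    if (nc != 10L) stop("narrowPeak needs exactly 10 columns, got ", nc, ": ", path)
  }
  start <- as.integer(dt[[2]]); end <- as.integer(dt[[3]])
  bad <- which(!(start >= 0L & start < end))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: invalid interval start=%d end=%d",
                 basename(path), bad[1], start[bad[1]], end[bad[1]]))
  }
  name <- if (nc >= 4L) as.character(dt[[4]]) else paste0("iv", seq_len(nrow(dt)))
  strand <- if (nc >= 6L) as.character(dt[[6]]) else rep(".", nrow(dt))
  iv <- genomic_intervals(dt[[1]], start, end, strand, name)
  if (kind == "bed6") {
    iv$score <- if (nc >= 5L) as.numeric(dt[[5]]) else 0
    return(iv[, c("chrom", "start", "end", "name", "score", "strand")])
  }
  iv$score <- as.integer(dt[[5]])
  iv$signal <- as.numeric(dt[[7]])
  iv$pvalue_log <- as.numeric(dt[[8]])
  iv$qvalue_log <- as.numeric(dt[[9]])
  summit <- as.integer(dt[[10]])
  len <- end - start
  bad <- which(!(summit == -1L | (summit >= 0L & summit < len)))
  if (length(bad) > 0L) {
    stop(sprintf("%s line %d: summit offset %d outside peak of length %d",
                 basename(path), bad[1], summit[bad[1]], len[bad[1]]))
  }
  iv$summit_offset <- summit
  iv[, c("chrom", "start", "end", "name", "score", "strand",
         "signal", "pvalue_log", "qvalue_log", "summit_offset")]
}

#' Write BED6 or narrowPeak records
#' @param x Table as returned by \code{\link{read_bed}}.
#' @param path Output path.
#' @param kind "bed6" or "narrowPeak".
#' @export
write_bed <- function(x, path, kind = c("bed6", "narrowPeak")) {
  kind <- match.arg(kind)
  cols <- if (kind == "bed6") {
    c("chrom", "start", "end", "name", "score", "strand")
  } else {
    c("chrom", "start", "end", "name", "score", "strand",
      "signal", "pvalue_log", "qvalue_log", "summit_offset")
  }
  if (!"score" %in% names(x)) x$score <- 0L
  data.table::fwrite(x[, cols], path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a CAGE tag table
#'
#' Expected TSV columns: element_id, library_id, strand, rel_position, count.
#' Lines starting with '#' are metadata and skipped.
#' @param path TSV path.
#' @return data.frame with those columns, counts validated >= 0.
#' @export
read_tag_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("element_id", "library_id", "strand", "rel_position", "count")
  if (!all(need %in% names(dt))) {
    stop("tag table missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  }
  dt$count <- as.integer(dt$count)
  if (any(dt$count < 0L)) stop("negative tag count in ", path)
  dt[, need]
}

#' Read a library-to-group map
#'
#' Expected TSV columns: library_id, group, class (tissue | primary_cell | other).
#' @param path TSV path.
#' @return data.frame with one row per library.
#' @export
read_library_map <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("library_id", "group", "class")
  if (!all(need %in% names(dt))) {
    stop("library map missing columns: ", paste(setdiff(need, names(dt)), collapse = ", "))
  }
  if (anyDuplicated(dt$library_id)) stop("duplicated library_id in ", path)
  dt[, need]
}

#' Write a results table as TSV with '#'-prefixed metadata lines
#' @param x data.frame.
#' @param path Output path.
#' @param meta Named character vector written as '# key: value' lines.
#' @export
write_tsv_report <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0L) {
    lines <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

REVCOMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a nucleotide string
#' @param seq Character scalar over A,C,G,T,N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract an anchored sequence window around a reference point
#'
#' Returns the sequence covering relative positions
#' \code{[-upstream, +downstream]} (inclusive at both ends) in the frame of the
#' element's strand: position 0 is the anchor base and negative positions are
#' upstream in the transcription direction. On the "-" strand the returned
#' sequence is reverse-complemented so that relative coordinates increase with
#' transcription.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param anchor Absolute 0-based position of the reference base (TSS or
#'   enhancer midpoint).
#' @param strand "+" or "-" (a "." is treated as "+").
#' @param upstream,downstream Non-negative extents in nt.
#' @return An object of class \code{anchored_seq}: list with fields
#'   \code{chrom}, \code{anchor}, \code{strand}, \code{seq},
#'   \code{rel_start}, \code{rel_end} (achieved relative range after any
#'   clipping) and \code{clipped} flag.
#' @export
extract_anchored <- function(genome, chrom, anchor, strand = "+",
                             upstream = 500L, downstream = 200L) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  chrlen <- nchar(genome[[chrom]])
  anchor <- as.integer(anchor)
  if (anchor < 0L || anchor >= chrlen) stop("anchor outside chromosome bounds")
  if (strand == ".") strand <- "+"
  if (strand == "+") {
    abs_start <- anchor - upstream
    abs_end <- anchor + downstream          # inclusive
  } else {
    abs_start <- anchor - downstream
    abs_end <- anchor + upstream
  }
  clipped <- abs_start < 0L || abs_end > chrlen - 1L
  abs_start_c <- max(abs_start, 0L)
  abs_end_c <- min(abs_end, chrlen - 1L)
  raw <- substr(genome[[chrom]], abs_start_c + 1L, abs_end_c + 1L)
  if (strand == "+") {
    rel_start <- abs_start_c - anchor
    rel_end <- abs_end_c - anchor
    seq <- raw
  } else {
    seq <- revcomp(raw)
    rel_start <- anchor - abs_end_c
    rel_end <- anchor - abs_start_c
  }
  structure(list(chrom = chrom, anchor = anchor, strand = strand, seq = seq,
                 rel_start = rel_start, rel_end = rel_end, clipped = clipped),
            class = "anchored_seq")
}

#' Convert a relative position in an anchored frame to an absolute position
#' @param anchored An \code{anchored_seq}.
#' @param rel Relative position(s).
#' @return Absolute 0-based genome position(s).
#' @export
anchored_to_absolute <- function(anchored, rel) {
  if (anchored$strand == "-") anchored$anchor - rel else anchored$anchor + rel
}
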
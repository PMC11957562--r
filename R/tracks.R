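#' Stranded per-base signal track
#'
#' Paired plus/minus per-base vectors over the circular contig. `kind` is
#' one of `"five_prime"` (base-resolution 5'-end counts, the profile model
#' target), `"coverage"` (full read-body coverage, used for screening and
#' plots) or `"predicted"` (model output).
#'
#' @param genome_name contig identifier.
#' @param kind track kind, see Description.
#' @param plus,minus numeric vectors of equal length, all values `>= 0`.
#' @return an object of class `stranded_track`.
#' @export
stranded_track <- function(genome_name, kind, plus, minus) {
  kind <- match.arg(kind, c("five_prime", "coverage", "predicted"))
  if (length(plus) != length(minus)) {
    stop("plus and minus vectors must have equal length")
  }
  if (any(plus < 0) || any(minus < 0)) stop("track values must be >= 0")
  structure(list(genome_name = as.character(genome_name), kind = kind,
                 plus = as.numeric(plus), minus = as.numeric(minus)),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  cat(sprintf("<stranded_track:%s> %s: %d bp, plus sum %.1f, minus sum %.1f\n",
              x$kind, x$genome_name, length(x$plus), sum(x$plus),
              sum(x$minus)))
  invisible(x)
}

#' Load alignments from SAM/BAM
#'
#' Unmapped and secondary records are skipped. For paired-end data PCR
#' duplicates are collapsed to one representative per duplicate key
#' (position, strand, template length), keeping the first record in file
#' order; for single-end data all mapped reads are retained, because no
#' dependable single-end duplicate-removal method exists that does not also
#' remove genuine signal at sharp sites. Reads are taken as aligned; no
#' re-alignment or MAPQ filtering is applied (the upstream aligner's
#' unique-mapping settings, e.g. bowtie `-v 2 -k 2 -m 1 -t --best
#' --strata` for 1x36mers against a mitochondria-only index, are an
#' external contract documented here for users processing real data).
#'
#' @param path SAM or BAM file containing the single circular contig.
#' @param genome_name expected contig name; a mismatch is an error naming
#'   both contigs.
#' @param paired whether records are paired-end (enables duplicate removal).
#' @return an [alignment_set()]; a zero-read file yields an empty set with a
#'   warning.
#' @export
load_alignments <- function(path, genome_name, paired = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such alignment file: %s", path))
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(genome_name %in% names(hdr))) {
    stop(sprintf("alignment file contig(s) '%s' do not include expected genome '%s'",
                 paste(names(hdr), collapse = ","), genome_name))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("pos", "strand", "qwidth", "isize", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(rec$pos)
  df <- data.frame(start = rec$pos[keep] - 1L,
                   length = rec$qwidth[keep],
                   strand = as.character(rec$strand[keep]),
                   isize = rec$isize[keep],
                   stringsAsFactors = FALSE)
  dedup <- FALSE
  if (paired && nrow(df) > 0) {
    key <- paste(df$start, df$strand, ifelse(is.na(df$isize), 0L, df$isize))
    df <- df[!duplicated(key), , drop = FALSE]
    dedup <- TRUE
  }
  if (nrow(df) == 0) {
    warning(sprintf("no mapped reads on %s in %s", genome_name, path))
  }
  df$isize <- NULL
  rownames(df) <- NULL
  alignment_set(genome_name, df, paired = paired, dedup_applied = dedup)
}

#' Base-resolution 5'-end track
#'
#' Counts read 5'-end positions per base and strand. The 5' end of a
#' plus-strand read is its leftmost coordinate; for a minus-strand read it
#' is the rightmost aligned base, `(start + length - 1) mod L`. The
#' conservation identity `sum(plus) + sum(minus) == number of reads` always
#' holds.
#'
#' @param aset an [alignment_set()].
#' @param genome_length length of the circular contig.
#' @return a [stranded_track()] of kind `"five_prime"`.
#' @export
five_prime_track <- function(aset, genome_length) {
  r <- aset$reads
  plus <- numeric(genome_length)
  minus <- numeric(genome_length)
  ip <- r$strand == "+"
  if (any(ip)) {
    t1 <- tabulate(mod_pos(r$start[ip], genome_length) + 1L, genome_length)
    plus <- plus + t1
  }
  if (any(!ip)) {
    five <- mod_pos(r$start[!ip] + r$length[!ip] - 1L, genome_length)
    minus <- minus + tabulate(five + 1L, genome_length)
  }
  stranded_track(aset$genome_name, "five_prime", plus, minus)
}

#' Full-coverage track
#'
#' Per-base count of read bodies overlapping each position, by strand, with
#' modular wrap past the origin.
#'
#' @inheritParams five_prime_track
#' @return a [stranded_track()] of kind `"coverage"`.
#' @export
coverage_track <- function(aset, genome_length) {
  cov_one <- function(starts, lengths) {
    out <- numeric(genome_length)
    if (length(starts) == 0) return(out)
    d <- numeric(genome_length + 1L)
    s <- mod_pos(starts, genome_length)
    e <- s + lengths  # exclusive
    wraps <- e > genome_length
    ## non-wrapping part
    d_idx <- s + 1L
    tabadd <- function(v, idx) v + tabulate(idx, length(v))
    d <- tabadd(d, d_idx)
    d_end <- pmin(e, genome_length) + 1L
    d <- d - tabulate(d_end, genome_length + 1L)
    out <- cumsum(d[seq_len(genome_length)])
    if (any(wraps)) {
      d2 <- numeric(genome_length + 1L)
      d2 <- tabadd(d2, rep(1L, sum(wraps)))
      d2 <- d2 - tabulate(e[wraps] - genome_length + 1L, genome_length + 1L)
      out <- out + cumsum(d2[seq_len(genome_length)])
    }
    out
  }
  r <- aset$reads
  ip <- r$strand == "+"
  stranded_track(aset$genome_name, "coverage",
                 cov_one(r$start[ip], r$length[ip]),
                 cov_one(r$start[!ip], r$length[!ip]))
}

#' Rotate a stranded track on the circle
#'
#' @param track a [stranded_track()].
#' @param r rotation offset (position `r` becomes position 0).
#' @return the rotated track.
#' @export
rotate_track <- function(track, r) {
  track$plus <- rotate_vec(track$plus, r)
  track$minus <- rotate_vec(track$minus, r)
  track
}

#' Write / read a stranded track as a bedGraph pair
#'
#' One bedGraph per strand (`<prefix>.plus.bedGraph`,
#' `<prefix>.minus.bedGraph`), with runs of equal value merged. The round
#' trip through [read_track()] is lossless; negative values in a file are
#' rejected on read.
#'
#' @param track a [stranded_track()].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_track <- function(track, prefix) {
  pp <- paste0(prefix, ".plus.bedGraph")
  pm <- paste0(prefix, ".minus.bedGraph")
  .write_bedgraph(track$plus, track$genome_name, pp)
  .write_bedgraph(track$minus, track$genome_name, pm)
  invisible(c(pp, pm))
}

#' @rdname write_track
#' @param genome_name expected contig name (checked if non-NULL).
#' @param kind track kind to restore.
#' @export
read_track <- function(prefix, genome_name = NULL, kind = "coverage") {
  vp <- .read_bedgraph(paste0(prefix, ".plus.bedGraph"), genome_name)
  vm <- .read_bedgraph(paste0(prefix, ".minus.bedGraph"), genome_name)
  if (any(vp$values < 0) || any(vm$values < 0)) {
    stop("negative values are not valid in a stranded track")
  }
  stranded_track(vp$genome_name, kind, vp$values, vm$values)
}
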
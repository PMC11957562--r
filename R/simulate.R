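#' Ground-truth occupancy and artifact sites
#'
#' @param position 0-based site anchors (fragment midpoints for occupancy
#'   sites, blob centers for artifacts; also the motif start when a motif is
#'   planted).
#' @param strand one of `"+"`, `"-"`, `"both"` per site; artifact sites must
#'   be `"both"`.
#' @param motif consensus string per site (`NA` if none).
#' @param enrichment expected fold over background, `>= 1`.
#' @param kind `"occupancy"` or `"artifact"`.
#' @return a data.frame of class `truth_sites`.
#' @export
truth_sites <- function(position, strand = "+", motif = NA_character_,
                        enrichment = 20, kind = "occupancy") {
  n <- length(position)
  df <- data.frame(position = as.integer(position),
                   strand = rep_len(as.character(strand), n),
                   motif = rep_len(as.character(motif), n),
                   enrichment = rep_len(as.numeric(enrichment), n),
                   kind = rep_len(as.character(kind), n),
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% c("occupancy", "artifact"))) {
    stop("kind must be 'occupancy' or 'artifact'")
  }
  if (!all(df$strand %in% c("+", "-", "both"))) {
    stop("strand must be '+', '-' or 'both'")
  }
  if (any(df$kind == "artifact" & df$strand != "both")) {
    stop("artifact sites must have strand 'both'")
  }
  if (any(df$enrichment < 1)) stop("enrichment must be >= 1")
  class(df) <- c("truth_sites", "data.frame")
  df
}

#' Plant motif instances into a circular genome
#'
#' For each occupancy placement the motif (reverse-complemented on the minus
#' strand) is written into the sequence starting at `position`, wrapping
#' across the origin if needed. Artifact placements do not modify the
#' sequence: the D-loop-like artifact the screen must reject is a library
#' artifact, not a sequence feature.
#'
#' @param genome a [circular_genome()].
#' @param motif consensus string, length >= 4.
#' @param placements data.frame with columns `position`, `strand`,
#'   `enrichment`, `kind`.
#' @return list with the modified `genome` and the recorded `sites`
#'   ([truth_sites()]).
#' @export
plant_motifs <- function(genome, motif, placements) {
  motif <- toupper(motif)
  if (nchar(motif) < 4L) stop("motif length must be >= 4")
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  len <- genome$length
  placements$position <- mod_pos(placements$position, len)
  occ <- placements[placements$kind == "occupancy", , drop = FALSE]
  if (nrow(occ) > 1) {
    idx <- unlist(lapply(occ$position, function(p)
      mod_pos(seq.int(p, length.out = nchar(motif)), len)))
    if (anyDuplicated(idx)) stop("overlapping occupancy placements are not allowed")
  }
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(occ))) {
    m <- if (occ$strand[i] == "-") reverse_complement(motif) else motif
    chars[circ_index(occ$position[i], nchar(m), len)] <-
      strsplit(m, "", fixed = TRUE)[[1]]
  }
  g2 <- circular_genome(genome$name, paste(chars, collapse = ""),
                        annotations = genome$annotations,
                        duplications = genome$duplications)
  sites <- truth_sites(placements$position, placements$strand,
                       motif = ifelse(placements$kind == "occupancy", motif,
                                      NA_character_),
                       enrichment = placements$enrichment,
                       kind = placements$kind)
  list(genome = g2, sites = sites)
}

#' Simulation configuration
#'
#' @param n_reads total number of single-end reads to emit.
#' @param read_length read length in bases (default 36, the 1x36mer
#'   convention of the screened libraries).
#' @param fragment_length_mean,fragment_length_sd sonication fragment length
#'   model (Gaussian, truncated below at `read_length`). The plus/minus
#'   5'-end summits of an occupancy site end up separated by
#'   `fragment_length_mean`.
#' @param background_fraction fraction of reads drawn uniformly from the
#'   circle; the remainder is split across sites proportionally to their
#'   `enrichment` weights.
#' @param seed integer seed; all randomness flows from it.
#' @param control if `TRUE`, site enrichment is suppressed and all reads are
#'   uniform background (an input/control library).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_reads, read_length = 36, fragment_length_mean = 200,
                       fragment_length_sd = 30, background_fraction = 0.5,
                       seed = 1, control = FALSE) {
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (read_length < 1) stop("read_length must be >= 1")
  if (fragment_length_mean < read_length) {
    stop("fragment_length_mean must be >= read_length")
  }
  if (background_fraction < 0 || background_fraction > 1) {
    stop("background_fraction must lie in [0, 1]")
  }
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 background_fraction = background_fraction,
                 seed = as.integer(seed), control = isTRUE(control)),
            class = "sim_config")
}

#' Alignment-set container
#'
#' @param genome_name contig the reads are aligned to.
#' @param reads data.frame with columns `start` (0-based leftmost), `length`,
#'   `strand` (`"+"`/`"-"`).
#' @param paired whether the records are paired-end.
#' @param dedup_applied whether duplicate removal has been applied.
#' @return an object of class `alignment_set`.
#' @export
alignment_set <- function(genome_name, reads, paired = FALSE,
                          dedup_applied = FALSE) {
  stopifnot(all(c("start", "length", "strand") %in% names(reads)))
  if (nrow(reads) > 0) {
    if (any(reads$length < 1)) stop("read lengths must be >= 1")
    if (!all(reads$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  }
  structure(list(genome_name = as.character(genome_name), reads = reads,
                 paired = isTRUE(paired), dedup_applied = isTRUE(dedup_applied)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d read(s) on %s (%s, dedup=%s)\n",
              nrow(x$reads), x$genome_name,
              if (x$paired) "paired" else "single-end", x$dedup_applied))
  invisible(x)
}

## 5'-end positions of an occupancy site's reads: a fragment of length f is
## centered on the site; sequencing one end gives a plus read starting
## f/2 upstream or a minus read whose 5' end is f/2 downstream.
.site_reads_occupancy <- function(n, site, cfg, len) {
  f <- pmax(cfg$read_length,
            round(stats::rnorm(n, cfg$fragment_length_mean,
                               cfg$fragment_length_sd)))
  side <- sample(c("+", "-"), n, replace = TRUE)
  five <- ifelse(side == "+",
                 site$position - round(f / 2),
                 site$position + round(f / 2))
  start <- ifelse(side == "+", five, five - cfg$read_length + 1L)
  data.frame(start = mod_pos(round(start), len),
             length = rep(cfg$read_length, n), strand = side,
             stringsAsFactors = FALSE)
}

## D-loop-like artifact: both strands drawn from the same symmetric Gaussian
## around the site, no strand offset.
.site_reads_artifact <- function(n, site, cfg, len) {
  sd_blob <- cfg$fragment_length_mean / 2
  five <- round(stats::rnorm(n, site$position, sd_blob))
  side <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(side == "+", five, five - cfg$read_length + 1L)
  data.frame(start = mod_pos(round(start), len),
             length = rep(cfg$read_length, n), strand = side,
             stringsAsFactors = FALSE)
}

#' Simulate single-end ChIP-seq reads on a circular genome
#'
#' Emits exactly `config$n_reads` aligned records. Background reads are
#' uniform on the circle. Occupancy sites produce the hallmark asymmetric
#' pattern: plus-strand 5' ends pile up about half a fragment length
#' upstream, minus-strand 5' ends the same distance downstream. Artifact
#' sites produce strand-symmetric enrichment with no offset. Coordinates
#' wrap modulo the genome length; output is deterministic given
#' `config$seed`.
#'
#' @param genome a [circular_genome()].
#' @param sites a [truth_sites()] data.frame (may be empty).
#' @param config a [sim_config()].
#' @return an [alignment_set()].
#' @export
simulate_reads <- function(genome, sites = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  len <- genome$length
  if (len <= 0) stop("genome must be non-empty")
  if (is.null(sites)) sites <- truth_sites(integer(0))[0, ]
  if (nrow(sites) > 0 && any(sites$position < 0 | sites$position >= len)) {
    stop("sites outside the genome")
  }
  n <- config$n_reads
  with_seed(config$seed, {
    if (nrow(sites) == 0 || config$control) {
      n_bg <- n
      n_site <- integer(0)
    } else {
      n_bg <- round(n * config$background_fraction)
      w <- sites$enrichment / sum(sites$enrichment)
      n_site <- if (n - n_bg > 0) {
        as.integer(stats::rmultinom(1, n - n_bg, w))
      } else rep(0L, nrow(sites))
    }
    parts <- list()
    if (n_bg > 0) {
      parts[[length(parts) + 1L]] <- data.frame(
        start = sample.int(len, n_bg, replace = TRUE) - 1L,
        length = rep(config$read_length, n_bg),
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(n_site)) {
      if (n_site[i] == 0) next
      s <- sites[i, ]
      parts[[length(parts) + 1L]] <- if (s$kind == "artifact") {
        .site_reads_artifact(n_site[i], s, config, len)
      } else {
        .site_reads_occupancy(n_site[i], s, config, len)
      }
    }
    reads <- if (length(parts)) do.call(rbind, parts) else {
      data.frame(start = integer(0), length = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    }
    alignment_set(genome$name, reads)
  })
}

#' Rotate all read coordinates on the circle
#'
#' @param aset an [alignment_set()].
#' @param r rotation offset (position `r` becomes position 0).
#' @param genome_length genome length in bases.
#' @return the rotated [alignment_set()].
#' @export
rotate_reads <- function(aset, r, genome_length) {
  aset$reads$start <- mod_pos(aset$reads$start - r, genome_length)
  aset
}

#' Write simulated alignments as SAM
#'
#' Produces a minimal single-contig SAM file (convertible to BAM with
#' [Rsamtools::asBam()]). Reads whose bodies wrap past the origin keep their
#' true start; their SEQ field is the circular reference substring, which
#' standard parsers accept even though the record extends past the nominal
#' contig end.
#'
#' @param aset an [alignment_set()].
#' @param genome the [circular_genome()] the reads came from.
#' @param path output `.sam` path.
#' @param to_bam if `TRUE`, also convert to a sorted, indexed BAM next to
#'   `path` and return the BAM path.
#' @return the path written, invisibly.
#' @export
write_alignments_sam <- function(aset, genome, path, to_bam = FALSE) {
  reads <- aset$reads
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length))
  lines <- character(nrow(reads))
  if (nrow(reads) > 0) {
    flag <- ifelse(reads$strand == "-", 16L, 0L)
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    seqs <- vapply(seq_len(nrow(reads)), function(i) {
      paste(chars[circ_index(reads$start[i], reads$length[i],
                             genome$length)], collapse = "")
    }, character(1))
    lines <- sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     seq_len(nrow(reads)), flag, genome$name,
                     reads$start + 1L, reads$length, seqs)
  }
  writeLines(c(header, lines), path)
  if (to_bam) {
    bam <- Rsamtools::asBam(path, sub("\\.sam$", "", path),
                            overwrite = TRUE, indexDestination = TRUE)
    return(invisible(bam))
  }
  invisible(path)
}

#' Write / read truth sites as BED
#'
#' 0-based half-open BED with `kind` and `enrichment` carried in the name
#' and score-side columns; a feature wrapping the origin is split into two
#' BED lines sharing one name. Round-trips losslessly through
#' [read_truth()].
#'
#' @param sites a [truth_sites()] data.frame.
#' @param path output path.
#' @param genome_name contig name for column 1.
#' @param genome_length genome length (needed to split wrap-spanning sites).
#' @param width feature width per site (defaults to motif length, or 1).
#' @return `path`, invisibly.
#' @export
write_truth <- function(sites, path, genome_name, genome_length,
                        width = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tkind\tenrichment\tmotif",
             con)
  if (nrow(sites) == 0) return(invisible(path))
  if (is.null(width)) {
    width <- ifelse(is.na(sites$motif), 1L, nchar(sites$motif))
  }
  width <- rep_len(as.integer(width), nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites$position[i]
    e <- s + width[i]
    nm <- sprintf("site%03d", i)
    strand_bed <- if (sites$strand[i] == "both") "." else sites$strand[i]
    seg <- if (e <= genome_length) {
      cbind(s, e)
    } else {
      rbind(c(s, genome_length), c(0L, e - genome_length))
    }
    for (j in seq_len(nrow(seg))) {
      writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%g\t%s", genome_name,
                         seg[j, 1], seg[j, 2], nm, strand_bed,
                         sites$kind[i], sites$enrichment[i],
                         ifelse(is.na(sites$motif[i]), ".", sites$motif[i])),
                 con)
    }
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path, genome_length) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) return(truth_sites(integer(0))[0, ])
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "kind",
                                        "enrichment", "motif"),
                          stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$name), function(seg) {
    ## a wrap-split feature has its first segment ending at the contig end
    first <- if (nrow(seg) == 2) {
      seg[seg$end == genome_length, , drop = FALSE]
    } else seg
    data.frame(position = first$start[1],
               strand = ifelse(first$strand[1] == ".", "both",
                               first$strand[1]),
               kind = first$kind[1], enrichment = first$enrichment[1],
               motif = ifelse(first$motif[1] == ".", NA_character_,
                              first$motif[1]),
               stringsAsFactors = FALSE)
  }))
  sites <- truth_sites(out$position, out$strand, out$motif, out$enrichment,
                       out$kind)
  rownames(sites) <- NULL
  sites
}
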
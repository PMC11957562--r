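#' Circular genome container
#'
#' A single circular contig with its sequence, labelled annotation intervals
#' (genes, the D-loop/control-region mask) and any planted duplications.
#' All coordinates are 0-based half-open and reduced modulo the genome
#' length; intervals spanning the origin are carried as (start, width) with
#' start < length.
#'
#' @param name contig identifier, e.g. `"chrM"`.
#' @param sequence character scalar over the alphabet `{A,C,G,T,N}`.
#' @param annotations optional data.frame with columns `start`, `width`,
#'   `label`.
#' @param duplications optional data.frame with columns `source_start`,
#'   `width`, `dest_start` describing planted exact repeats.
#' @return an object of class `circular_genome` with fields `name`,
#'   `sequence`, `length`, `circular`, `annotations`, `duplications`.
#' @export
circular_genome <- function(name, sequence, annotations = NULL,
                            duplications = NULL) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence alphabet must be a subset of {A,C,G,T,N}")
  }
  len <- nchar(sequence)
  if (is.null(annotations)) {
    annotations <- data.frame(start = integer(0), width = integer(0),
                              label = character(0))
  }
  if (nrow(annotations) > 0) {
    if (any(annotations$width <= 0)) stop("annotation widths must be positive")
    annotations$start <- mod_pos(annotations$start, len)
  }
  if (is.null(duplications)) {
    duplications <- data.frame(source_start = integer(0), width = integer(0),
                               dest_start = integer(0))
  }
  structure(
    list(name = as.character(name), sequence = sequence, length = len,
         circular = TRUE, annotations = annotations,
         duplications = duplications),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp, %d annotation(s), %d duplication(s)\n",
              x$name, x$length, nrow(x$annotations), nrow(x$duplications)))
  invisible(x)
}

#' Generate a random circular genome
#'
#' Samples an i.i.d. sequence at the requested GC content and then pastes in
#' exact duplicated segments (NUMT-like repeats) so that mappability
#' computations have known multi-mapping regions. Deterministic given
#' `seed`.
#'
#' @param length genome length in bases (> 0).
#' @param gc_content target GC fraction, strictly between 0 and 1.
#' @param duplications list of length-3 vectors
#'   `c(source_start, width, dest_start)` (0-based), applied in order after
#'   the random sequence is drawn. Segments may wrap around the origin.
#' @param seed integer seed; identical seeds give byte-identical sequences.
#' @param name contig identifier.
#' @return a [circular_genome()].
#' @examples
#' g <- generate_circular_genome(1000, gc_content = 0.5, seed = 1)
#' g$length
#' @export
generate_circular_genome <- function(length, gc_content = 0.44,
                                     duplications = list(), seed = 1,
                                     name = "chrM_sim") {
  if (length <= 0) stop("genome length must be positive")
  if (gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must lie strictly between 0 and 1")
  }
  length <- as.integer(length)
  base <- c("A", "C", "G", "T")
  prob <- c((1 - gc_content) / 2, gc_content / 2,
            gc_content / 2, (1 - gc_content) / 2)
  chars <- with_seed(seed, sample(base, length, replace = TRUE, prob = prob))
  dup_df <- data.frame(source_start = integer(0), width = integer(0),
                       dest_start = integer(0))
  for (d in duplications) {
    d <- as.integer(d)
    if (length(d) != 3L) stop("each duplication must be (source_start, width, dest_start)")
    if (d[2] <= 0 || d[2] > length) {
      stop(sprintf("duplication of width %d does not fit in a %d bp genome",
                   d[2], length))
    }
    src <- circ_index(d[1], d[2], length)
    dst <- circ_index(d[3], d[2], length)
    chars[dst] <- chars[src]
    dup_df <- rbind(dup_df, data.frame(source_start = mod_pos(d[1], length),
                                       width = d[2],
                                       dest_start = mod_pos(d[3], length)))
  }
  circular_genome(name, paste(chars, collapse = ""), duplications = dup_df)
}

#' Extract a circular substring
#'
#' @param genome a [circular_genome()].
#' @param start 0-based start (any integer; reduced modulo length).
#' @param width number of bases; may wrap around the origin.
#' @return character scalar of `width` bases.
#' @export
subseq_circular <- function(genome, start, width) {
  idx <- circ_index(start, width, genome$length)
  paste(strsplit(genome$sequence, "", fixed = TRUE)[[1]][idx], collapse = "")
}

#' Rotate a circular genome
#'
#' Position `r` of the input becomes position 0 of the output; annotations
#' and duplications are shifted accordingly. Used mainly for the rotation
#' equivariance properties of downstream tracks.
#'
#' @param genome a [circular_genome()].
#' @param r rotation offset in bases.
#' @return the rotated [circular_genome()].
#' @export
rotate_genome <- function(genome, r) {
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  ann <- genome$annotations
  if (nrow(ann) > 0) ann$start <- mod_pos(ann$start - r, genome$length)
  dup <- genome$duplications
  if (nrow(dup) > 0) {
    dup$source_start <- mod_pos(dup$source_start - r, genome$length)
    dup$dest_start <- mod_pos(dup$dest_start - r, genome$length)
  }
  circular_genome(genome$name, paste(rotate_vec(chars, r), collapse = ""),
                  annotations = ann, duplications = dup)
}

#' Write / read a circular genome as FASTA
#'
#' @param genome a [circular_genome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) {
    stop(sprintf("expected a single circular contig in %s, found %d records",
                 path, length(ss)))
  }
  circular_genome(names(ss)[1], as.character(ss[[1]]))
}
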
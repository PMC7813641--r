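#' Create a circular (or linear) genome record
#'
#' The basic sequence container used throughout the package: an identifier,
#' an upper-case DNA string over `A,C,G,T,N`, and a declared topology.
#' Mitochondrial genomes are circular, so all downstream coordinate
#' arithmetic (windows, repeat scans, gene adjacencies) wraps modulo the
#' genome length when `topology == "circular"`.
#'
#' @param sequence A single DNA string (case-insensitive; `A,C,G,T,N` only).
#' @param id Identifier for the genome.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `circular_genome`: a list with elements
#'   `id`, `sequence` and `topology`.
#' @examples
#' g <- circular_genome("ACGTACGTAA", id = "toy")
#' genome_length(g)
#' @export
circular_genome <- function(sequence, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("genome sequence must have length >= 1", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop(
      "sequence contains characters outside {A,C,G,T,N}: ",
      paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(id = as.character(id), sequence = sequence, topology = topology),
    class = "circular_genome"
  )
}

#' @export
print.circular_genome <- function(x, ...) {
  n <- genome_length(x)
  head_seq <- substr(x$sequence, 1L, min(40L, n))
  cat(sprintf(
    "<circular_genome> %s: %s bp, %s (GC %.1f%%)\n  %s%s\n",
    x$id, format(n, big.mark = ","), x$topology, 100 * gc_fraction(x$sequence),
    head_seq, if (n > 40L) "..." else ""
  ))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome A `circular_genome` or a DNA string.
#' @return Integer length.
#' @export
genome_length <- function(genome) {
  nchar(as_dna_string(genome))
}

#' @export
length.circular_genome <- function(x) genome_length(x)

is_circular <- function(genome) {
  inherits(genome, "circular_genome") && identical(genome$topology, "circular")
}

as_dna_string <- function(x) {
  if (inherits(x, "circular_genome")) return(x$sequence)
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    return(toupper(as.character(x)[1]))
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Reverse complement of a DNA string
#'
#' `N` complements to `N`.
#'
#' @param x DNA string, `circular_genome`, or character vector of strings.
#' @return Character vector of reverse-complemented strings.
#' @export
dna_revcomp <- function(x) {
  if (inherits(x, "circular_genome")) x <- x$sequence
  vapply(
    toupper(x),
    function(s) {
      chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    },
    character(1),
    USE.NAMES = FALSE
  )
}

# GC fraction over non-N bases; NA when no informative base.
gc_fraction <- function(seq_chr) {
  b <- strsplit(toupper(seq_chr), "")[[1]]
  informative <- b != "N"
  if (!any(informative)) return(NA_real_)
  sum(b == "G" | b == "C") / sum(informative)
}

#' Rotate the origin of a circular genome
#'
#' Returns the same circle transcribed from a new start point. Used for
#' rotation-invariance checks: repeat scans and gene orders must not depend
#' on where the deposited record happens to begin.
#'
#' @param genome A `circular_genome` with circular topology.
#' @param offset New origin, 0-based (the base at `offset` becomes base 0).
#' @return A rotated `circular_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!is_circular(genome)) stop("can only rotate a circular genome", call. = FALSE)
  n <- genome_length(genome)
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L) return(genome)
  s <- genome$sequence
  circular_genome(
    paste0(substr(s, offset + 1L, n), substr(s, 1L, offset)),
    id = genome$id, topology = "circular"
  )
}

# Rotate a feature table along with rotate_genome(). Intervals that come to
# straddle the new origin are split into two parts of one feature.
rotate_features <- function(features, offset, n) {
  offset <- ((as.integer(offset) %% n) + n) %% n
  if (offset == 0L || nrow(features) == 0L) return(features)
  out <- features
  out$start <- (features$start - offset) %% n
  out$end <- out$start + (features$end - features$start)
  split_rows <- which(out$end > n)
  if (length(split_rows) > 0L) {
    extra <- out[split_rows, , drop = FALSE]
    extra$start <- 0L
    extra$end <- out$end[split_rows] - n
    out$end[split_rows] <- n
    out <- dplyr::bind_rows(out, extra)
  }
  out <- dplyr::arrange(out, .data$feature_id, .data$part, .data$start)
  # renumber parts within features in genomic order of the split pieces
  out <- dplyr::group_by(out, .data$feature_id)
  out <- dplyr::mutate(out, part = dplyr::row_number())
  dplyr::ungroup(out)
}

#' Read a single-sequence FASTA file as a genome
#'
#' @param path FASTA file path.
#' @param id Optional identifier (defaults to the FASTA header).
#' @param topology `"circular"` or `"linear"`.
#' @return A `circular_genome`.
#' @export
read_fasta_genome <- function(path, id = NULL, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path, call. = FALSE)
  circular_genome(
    as.character(ss[[1]]),
    id = if (is.null(id)) sub("\\s.*$", "", names(ss)[1]) else id,
    topology = topology
  )
}

#' Write a genome to FASTA
#' @param genome A `circular_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
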
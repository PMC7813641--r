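#' Sliding-window GC profile
#'
#' GC fraction of `(G+C) / (non-N bases)` in windows anchored at 0, `step`,
#' `2*step`, ... On circular genomes the windows wrap the origin and the
#' profile has `ceiling(length / step)` windows; on linear genomes windows
#' must fit inside the sequence. All-N windows are emitted as `NA`.
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param window Window size in bp (default 100).
#' @param step Step size in bp (default 10).
#' @return A tibble of class `gc_profile` with columns `start` (0-based
#'   window anchor) and `gc` (fraction in `[0, 1]`).
#' @examples
#' gc_profile(circular_genome(strrep("GGAA", 100), "toy"))
#' @export
gc_profile <- function(genome, window = 100L, step = 10L) {
  if (is.character(genome)) genome <- circular_genome(genome, topology = "linear")
  n <- genome_length(genome)
  window <- as.integer(window)
  step <- as.integer(step)
  stopifnot(window >= 1L, step >= 1L)
  circ <- is_circular(genome)
  if (!circ && window > n) stop("window larger than linear genome", call. = FALSE)

  s <- genome$sequence
  if (circ) {
    reps <- ceiling((n + window) / n)
    s <- substr(strrep(s, reps), 1L, n + window)
  }
  b <- strsplit(s, "")[[1]]
  is_gc <- cumsum(c(0L, b == "G" | b == "C"))
  informative <- cumsum(c(0L, b != "N"))
  starts <- if (circ) seq.int(0L, n - 1L, by = step) else seq.int(0L, n - window, by = step)
  gc_cnt <- is_gc[starts + window + 1L] - is_gc[starts + 1L]
  inf_cnt <- informative[starts + window + 1L] - informative[starts + 1L]
  out <- tibble::tibble(
    start = as.integer(starts),
    gc = ifelse(inf_cnt == 0L, NA_real_, gc_cnt / inf_cnt)
  )
  attr(out, "genome_id") <- genome$id
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- unique(c("gc_profile", class(out)))
  out
}

#' Dotplot of two sequences by windowed ungapped scoring
#'
#' A point is emitted at `(i, j)` (0-based window starts) whenever the
#' ungapped alignment of the length-`window` words starting at `i` in `seqA`
#' and `j` in `seqB` scores at least `threshold` under the match/mismatch
#' scores (defaults +5/-4, the standard DNA scoring of dotplot tools).
#'
#' @param seq_a,seq_b DNA strings or [circular_genome()] objects (treated as
#'   linear word sources).
#' @param window Word length (default 50).
#' @param threshold Minimum window score (default 100).
#' @param match,mismatch Per-base scores (defaults +5 and -4).
#' @return A tibble with columns `i`, `j` and `score`.
#' @export
dotplot <- function(seq_a, seq_b, window = 50L, threshold = 100,
                    match = 5, mismatch = -4) {
  a <- strsplit(as_dna_string(seq_a), "")[[1]]
  b <- strsplit(as_dna_string(seq_b), "")[[1]]
  window <- as.integer(window)
  stopifnot(window >= 1L, threshold <= window * match)
  na <- length(a)
  nb <- length(b)
  if (na < window || nb < window) stop("both sequences must be >= window", call. = FALSE)

  pts <- list()
  for (off in seq.int(-(na - window), nb - window)) {
    ia <- seq.int(max(1L, 1L - off), min(na, nb - off))
    eq <- (a[ia] == b[ia + off]) & (a[ia] != "N")
    cs <- cumsum(c(0L, eq))
    starts <- seq_len(length(ia) - window + 1L)
    if (length(starts) == 0L) next
    nmatch <- cs[starts + window] - cs[starts]
    score <- match * nmatch + mismatch * (window - nmatch)
    hit <- which(score >= threshold)
    if (length(hit) > 0L) {
      i0 <- ia[1] + hit - 2L  # 0-based start in a
      pts[[length(pts) + 1L]] <- tibble::tibble(
        i = as.integer(i0), j = as.integer(i0 + off), score = score[hit]
      )
    }
  }
  if (length(pts) == 0L) {
    return(tibble::tibble(i = integer(), j = integer(), score = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(pts), .data$i, .data$j)
}

#' Pairwise p-distances with pairwise deletion
#'
#' For every pair of aligned sequences, the proportion of differing sites
#' over the columns where neither sequence has a gap or missing character
#' (`-`, `.`, `?`, `N`, or anything outside `A,C,G,T`). Pairs with zero
#' comparable sites get `NA`.
#'
#' @param alignment Equal-length aligned sequences: a named character
#'   vector, a `Biostrings::DNAStringSet`, an `ape::DNAbin` matrix, or a
#'   data frame with `label` and `sequence` columns.
#' @return An object of class `p_distance`: list with `distance` and
#'   `n_sites` (symmetric matrices) and `labels`.
#' @examples
#' p_distance(c(s1 = "ACGT", s2 = "AGGT", s3 = "AC-T"))
#' @export
p_distance <- function(alignment) {
  mat <- alignment_matrix(alignment)
  k <- nrow(mat)
  if (k < 2L) stop("need at least two aligned sequences", call. = FALSE)
  good <- mat %in% c("A", "C", "G", "T")
  dim(good) <- dim(mat)
  d <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  ns <- matrix(ncol(mat), k, k, dimnames = dimnames(d))
  for (x in seq_len(k - 1L)) {
    for (y in seq.int(x + 1L, k)) {
      ok <- good[x, ] & good[y, ]
      ns[x, y] <- ns[y, x] <- sum(ok)
      d[x, y] <- d[y, x] <- if (sum(ok) == 0L) {
        NA_real_
      } else {
        sum(mat[x, ok] != mat[y, ok]) / sum(ok)
      }
    }
  }
  structure(list(distance = d, n_sites = ns, labels = rownames(mat)),
            class = "p_distance")
}

alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAbin")) {
    alignment <- vapply(
      seq_len(nrow(alignment)),
      function(i) paste(toupper(as.character(alignment[i, ])), collapse = ""),
      character(1)
    ) |> stats::setNames(rownames(alignment))
  }
  if (inherits(alignment, "DNAStringSet")) {
    alignment <- stats::setNames(toupper(as.character(alignment)), names(alignment))
  }
  if (is.data.frame(alignment)) {
    alignment <- stats::setNames(toupper(alignment$sequence), alignment$label)
  }
  stopifnot(is.character(alignment))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("seq", seq_along(alignment))
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  mat
}

#' @export
print.p_distance <- function(x, ...) {
  cat(sprintf("<p_distance> %d sequences, %d aligned sites (pairwise deletion)\n",
              length(x$labels), max(x$n_sites)))
  print(round(x$distance, 4))
  invisible(x)
}

#' @rdname p_distance
#' @param x A `p_distance` object.
#' @param ... Unused.
#' @method tidy p_distance
#' @export
tidy.p_distance <- function(x, ...) {
  k <- length(x$labels)
  pairs <- which(upper.tri(x$distance), arr.ind = TRUE)
  tibble::tibble(
    label_a = x$labels[pairs[, 1]],
    label_b = x$labels[pairs[, 2]],
    distance = x$distance[pairs],
    n_sites = x$n_sites[pairs]
  )
}

#' @rdname p_distance
#' @method glance p_distance
#' @export
glance.p_distance <- function(x, ...) {
  up <- x$distance[upper.tri(x$distance)]
  tibble::tibble(
    n_sequences = length(x$labels),
    mean_distance = mean(up, na.rm = TRUE),
    max_distance = max(up, na.rm = TRUE)
  )
}
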
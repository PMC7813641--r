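#' Parameters for the tandem-repeat scan
#'
#' Scoring weights follow the classic tandem-repeat settings for
#' mitogenomes: match +2, mismatch and indel penalties 7, minimum alignment
#' score 50, maximum period 500, with the 80%/10% match/indel probabilities
#' used only to accept a consensus period.
#'
#' @param match Match weight (positive).
#' @param mismatch Mismatch penalty (positive number, subtracted).
#' @param indel Indel penalty (positive number, subtracted).
#' @param min_score Minimum wraparound alignment score to report.
#' @param max_period Maximum period size in bp.
#' @param match_probability Minimum identity for a consensus period to be
#'   accepted when minimizing the period.
#' @param indel_probability Retained for interface completeness.
#' @return A validated list of class `tandem_params`.
#' @export
tandem_params <- function(match = 2, mismatch = 7, indel = 7, min_score = 50,
                          max_period = 500L, match_probability = 0.80,
                          indel_probability = 0.10) {
  p <- list(match = match, mismatch = mismatch, indel = indel,
            min_score = min_score, max_period = as.integer(max_period),
            match_probability = match_probability,
            indel_probability = indel_probability)
  stopifnot(p$min_score > 0, p$max_period >= 1L)
  structure(p, class = "tandem_params")
}

#' Find tandem repeats by seeded wraparound-alignment scoring
#'
#' Candidate periods are seeded by exact k-mer recurrences at distance
#' `d <= max_period`; each candidate array is grown by period-consistency
#' (comparing each base with the base one period away, cutting the
#' extension at the running-score maximum), its consensus is inferred by
#' per-phase majority vote, the period is minimized to the smallest divisor
#' whose cyclic consensus still explains the array at
#' `match_probability` identity, and the array is scored by wraparound
#' alignment of everything beyond the first copy against the cyclic
#' consensus. A perfect array of span `s` and period `p` therefore scores
#' `match * (s - p)`. Overlapping reports of one array are merged to the
#' highest-scoring period.
#'
#' @param genome A [circular_genome()] or DNA string.
#' @param params A [tandem_params()] object.
#' @param seed_k Seed k-mer length (default 8).
#' @return A tibble with one row per reported repeat: `genome_id`, `start`,
#'   `end` (0-based half-open, unrolled for circular genomes), `period`,
#'   `copy_number`, `consensus`, `score`.
#' @examples
#' g <- paste0(strrep("TTAAC", 4), strrep("ACGT", 20), strrep("GATCA", 4))
#' find_tandem_repeats(g)
#' @export
find_tandem_repeats <- function(genome, params = tandem_params(), seed_k = 8L) {
  if (is.character(genome)) genome <- circular_genome(genome, topology = "linear")
  n <- genome_length(genome)
  circ <- is_circular(genome)
  s_chr <- genome$sequence
  if (circ) {
    ext_len <- min(2L * n, n + 2L * params$max_period)
    reps <- ceiling(ext_len / n) + 1L
    s_chr <- substr(strrep(s_chr, reps), 1L, ext_len)
  }
  b <- strsplit(s_chr, "")[[1]]
  m <- length(b)
  if (m < 2L * seed_k) return(empty_tandem_tbl())

  cand <- tandem_seeds(b, params$max_period, seed_k)
  if (nrow(cand) == 0L) return(empty_tandem_tbl())
  cand <- dplyr::arrange(cand, .data$pos, .data$period)

  reports <- list()
  covered <- rep(FALSE, m)
  for (i in seq_len(nrow(cand))) {
    pos <- cand$pos[i]
    d <- cand$period[i]
    if (covered[pos]) next
    arr <- grow_array(b, pos, d)
    if (is.null(arr)) next
    span_len <- arr$end - arr$start
    if (span_len / d < 1.9) next
    res <- call_array(b, arr$start, arr$end, d, params)
    if (is.null(res)) next
    if (circ && res$start >= n) next  # duplicate of an in-range report
    reports[[length(reports) + 1L]] <- res
    covered[seq(res$start + 1L, min(res$end, m))] <- TRUE
  }
  if (length(reports) == 0L) return(empty_tandem_tbl())
  out <- dplyr::bind_rows(reports)

  # merge overlapping reports of the same array: best score wins
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$period, .data$start)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      for (j in seq(i + 1L, nrow(out))) {
        if (keep[j] && out$start[j] < out$end[i] && out$end[j] > out$start[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out$genome_id <- genome$id
  if (circ) {
    len <- out$end - out$start
    out$start <- out$start %% n
    out$end <- out$start + len
  }
  out <- dplyr::arrange(out, .data$start)
  dplyr::select(out, "genome_id", "start", "end", "period", "copy_number",
                "consensus", "score")
}

empty_tandem_tbl <- function() {
  tibble::tibble(genome_id = character(), start = integer(), end = integer(),
                 period = integer(), copy_number = numeric(),
                 consensus = character(), score = numeric())
}

# Exact k-mer recurrence seeds: positions whose k-mer reappears at distance
# <= max_period downstream.
tandem_seeds <- function(b, max_period, k) {
  m <- length(b)
  if (m < 2L * k) return(tibble::tibble(pos = integer(), period = integer()))
  base4 <- c(A = 0L, C = 1L, G = 2L, T = 3L)[b]
  valid <- !is.na(base4)
  base4[!valid] <- 0L
  nk <- m - k + 1L
  code <- numeric(nk)
  pow <- 4^(seq_len(k) - 1L)
  for (j in seq_len(k)) {
    code <- code + base4[seq.int(j, j + nk - 1L)] * pow[k - j + 1L]
  }
  okk <- vapply(seq_len(nk), function(i) all(valid[i:(i + k - 1L)]), logical(1))
  pos_by_code <- split(which(okk), code[okk])
  out_pos <- integer(0)
  out_d <- integer(0)
  for (ps in pos_by_code) {
    if (length(ps) < 2L) next
    dd <- diff(ps)
    sel <- which(dd <= max_period)
    if (length(sel) > 0L) {
      out_pos <- c(out_pos, ps[sel])
      out_d <- c(out_d, dd[sel])
    }
  }
  unique(tibble::tibble(pos = out_pos, period = out_d))
}

# Grow an array around a seeded position by period consistency: compare each
# base with the base one period back, extend to the running-score maxima on
# both sides (match +1, mismatch -3 on this internal scale).
grow_array <- function(b, pos, d) {
  m <- length(b)
  right_limit <- m
  j <- pos + d
  if (j > m) return(NULL)
  best_r <- pos + d - 1L  # guarantee at least one copy boundary
  run <- 0
  best_run <- 0
  jj <- j
  while (jj <= right_limit) {
    run <- run + (if (b[jj] == b[jj - d] && b[jj] != "N") 1 else -3)
    if (run >= best_run) {
      best_run <- run
      best_r <- jj
    }
    if (run < best_run - 12) break
    jj <- jj + 1L
  }
  run <- 0
  best_run <- 0
  best_l <- pos
  jj <- pos - 1L
  while (jj >= 1L && jj + d <= m) {
    run <- run + (if (b[jj] == b[jj + d] && b[jj] != "N") 1 else -3)
    if (run >= best_run) {
      best_run <- run
      best_l <- jj
    }
    if (run < best_run - 12) break
    jj <- jj - 1L
  }
  # 0-based half-open span
  list(start = best_l - 1L, end = best_r)
}

# Score a candidate array: majority-vote consensus, period minimization to
# the smallest divisor explaining the array at match_probability identity,
# wraparound alignment of everything beyond the first copy.
call_array <- function(b, start0, end0, d, params) {
  if (d > params$max_period) return(NULL)
  span <- b[(start0 + 1L):end0]
  len <- length(span)
  consensus_for <- function(p) {
    phases <- ((seq_len(len) - 1L) %% p) + 1L
    vapply(seq_len(p), function(ph) {
      tab <- table(span[phases == ph])
      tab <- tab[names(tab) != "N"]
      if (length(tab) == 0L) return("N")
      names(tab)[which.max(tab)]
    }, character(1))
  }
  identity_for <- function(cons) {
    p <- length(cons)
    mean(span == cons[((seq_len(len) - 1L) %% p) + 1L])
  }
  # candidate periods, smallest first: divisors whose consensus explains
  # the array at match_probability identity, then the seeded period itself.
  # The smallest candidate that also clears the score gate wins.
  divisors <- seq_len(d - 1L)
  divisors <- divisors[d %% divisors == 0L]
  for (p in c(divisors, d)) {
    if (len / p < 1.9) next
    cons <- consensus_for(p)
    if (p < d && identity_for(cons) < params$match_probability) next
    region <- span[(p + 1L):len]
    score <- wrap_align_cpp(
      dna_to_int(paste(region, collapse = "")),
      dna_to_int(paste(cons, collapse = "")),
      params$match, params$mismatch, params$indel
    )
    if (score >= params$min_score) {
      return(tibble::tibble(
        genome_id = NA_character_, start = start0, end = end0,
        period = as.integer(p), copy_number = round(len / p, 2),
        consensus = paste(cons, collapse = ""), score = score
      ))
    }
  }
  NULL
}

#' Recompute the wraparound alignment score of a reported repeat
#'
#' Self-consistency check used by the test-suite: the reported score must
#' equal the wraparound-alignment score of the array beyond its first copy
#' against its cyclic consensus.
#'
#' @param genome The genome the repeat was reported on.
#' @param repeat_row One row of the [find_tandem_repeats()] output.
#' @param params The [tandem_params()] used.
#' @return The recomputed numeric score.
#' @export
tandem_score <- function(genome, repeat_row, params = tandem_params()) {
  if (is.character(genome)) genome <- circular_genome(genome, topology = "linear")
  n <- genome_length(genome)
  pos <- (seq.int(repeat_row$start, repeat_row$end - 1L) %% n) + 1L
  b <- strsplit(genome$sequence, "")[[1]][pos]
  region <- b[(repeat_row$period + 1L):length(b)]
  wrap_align_cpp(
    dna_to_int(paste(region, collapse = "")),
    dna_to_int(repeat_row$consensus),
    params$match, params$mismatch, params$indel
  )
}
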
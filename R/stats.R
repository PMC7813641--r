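#' Summarize one genome's architecture
#'
#' Produces the per-genome summary row used in cohort tables: total size and
#' GC, coding and intergenic size/GC, intron class sizes and counts, and
#' count/total-bp statistics of small inverted repeats and tandem repeats
#' split into coding/intergenic by the midpoint rule.
#'
#' @param genome A [circular_genome()].
#' @param partition A [partition_regions()] result for it.
#' @param sir_hits A filtered, classified SIR hit tibble (e.g.
#'   `scan_sirs(...)$hits`), or `NULL`.
#' @param tandem A [find_tandem_repeats()] tibble, or `NULL`.
#' @return A one-row tibble.
#' @export
summarize_genome <- function(genome, partition, sir_hits = NULL, tandem = NULL) {
  n <- genome_length(genome)
  two_way <- function(x, start_col = "left_start", end_col = "right_end") {
    if (is.null(x) || nrow(x) == 0L) {
      return(list(n = 0L, n_cr = 0L, n_igr = 0L, bp = 0L, bp_cr = 0L, bp_igr = 0L))
    }
    if (!"midpoint_class" %in% names(x)) x <- assign_regions(x, partition)
    start <- if (start_col %in% names(x)) x[[start_col]] else x$start
    end <- if (end_col %in% names(x)) x[[end_col]] else x$end
    bp <- end - start
    cr <- x$midpoint_class == "coding"
    list(n = nrow(x), n_cr = sum(cr), n_igr = sum(!cr),
         bp = sum(bp), bp_cr = sum(bp[cr]), bp_igr = sum(bp[!cr]))
  }
  sir <- two_way(sir_hits)
  tr <- two_way(tandem, "start", "end")
  tibble::tibble(
    genome_id = genome$id,
    size_bp = n,
    gc_pct = 100 * gc_fraction(genome$sequence),
    coding_bp = unname(partition$sizes[["coding"]]),
    coding_gc_pct = 100 * unname(partition$gc[["coding"]]),
    igr_bp = unname(partition$sizes[["intergenic"]]),
    igr_gc_pct = 100 * unname(partition$gc[["intergenic"]]),
    introni_bp = unname(partition$sizes[["intronI"]]),
    introni_n = unname(partition$counts[["intronI"]]),
    intronii_bp = unname(partition$sizes[["intronII"]]),
    intronii_n = unname(partition$counts[["intronII"]]),
    sir_bp = sir$bp, sir_bp_cr = sir$bp_cr, sir_bp_igr = sir$bp_igr,
    sir_n = sir$n, sir_n_cr = sir$n_cr, sir_n_igr = sir$n_igr,
    tr_bp = tr$bp, tr_bp_cr = tr$bp_cr, tr_bp_igr = tr$bp_igr,
    tr_n = tr$n, tr_n_cr = tr$n_cr, tr_n_igr = tr$n_igr
  )
}

#' Column means and population standard deviations of a cohort table
#'
#' The spread statistic is the population standard deviation (divisor `n`,
#' not `n - 1`), the convention used in comparative mitogenome summary
#' tables.
#'
#' @param summaries A tibble of per-genome summaries (any numeric columns).
#' @return A tibble with one row per numeric column: `column`, `n`, `mean`,
#'   `sd` (population).
#' @examples
#' cohort_stats(tibble::tibble(x = c(1, 3)))
#' @export
cohort_stats <- function(summaries) {
  num_cols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  purrr::map_dfr(num_cols, function(cl) {
    x <- summaries[[cl]]
    x <- x[!is.na(x)]
    tibble::tibble(
      column = cl,
      n = length(x),
      mean = mean(x),
      sd = sqrt(mean((x - mean(x))^2))
    )
  })
}

#' One-tailed two-group comparison (Welch's t or Mann-Whitney U)
#'
#' `alternative = "greater"` tests whether group `a` tends to exceed group
#' `b`. The Welch test uses the Welch-Satterthwaite degrees of freedom; if
#' both groups have zero variance and equal means the one-tailed p-value is
#' reported as 0.5 by convention. The U test reports `U` counted as pairs
#' where `a > b` (ties count one half); the p-value is computed by exact
#' enumeration of all group assignments when the combined sample size is at
#' most 12 (ties handled exactly), and by the normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors.
#' @param test `"welch"` or `"mann_whitney"`.
#' @param alternative `"greater"` or `"less"` (one-tailed).
#' @return A one-row tibble: `method`, `alternative`, `statistic`, `df`
#'   (`NA` for U), `p_value`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13), test = "mann_whitney",
#'                alternative = "less")
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("welch", "mann_whitney"),
                           alternative = c("greater", "less")) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (test == "welch") {
    stopifnot(length(a) >= 2L, length(b) >= 2L)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) {
        rlang::inform("both groups constant and equal; one-tailed p = 0.5 by convention")
        return(result_row("welch_one_tailed", alternative, 0, NA_real_, 0.5, a, b))
      }
      p <- if ((mean(a) > mean(b)) == (alternative == "greater")) 0 else 1
      return(result_row("welch_one_tailed", alternative,
                        sign(mean(a) - mean(b)) * Inf, NA_real_, p, a, b))
    }
    ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
    return(result_row("welch_one_tailed", alternative,
                      unname(ht$statistic), unname(ht$parameter),
                      ht$p.value, a, b))
  }

  stopifnot(length(a) >= 1L, length(b) >= 1L)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  n <- length(a) + length(b)
  if (n <= 12L) {
    pool <- c(a, b)
    combs <- utils::combn(n, length(a))
    us <- apply(combs, 2, function(idx) u_of(pool[idx], pool[-idx]))
    p <- if (alternative == "greater") mean(us >= u_obs) else mean(us <= u_obs)
  } else {
    na <- length(a)
    nb <- length(b)
    mu <- na * nb / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    z <- if (alternative == "greater") {
      (u_obs - mu - 0.5) / sigma
    } else {
      (u_obs - mu + 0.5) / sigma
    }
    p <- if (alternative == "greater") {
      stats::pnorm(z, lower.tail = FALSE)
    } else {
      stats::pnorm(z)
    }
  }
  result_row("mann_whitney_one_tailed", alternative, u_obs, NA_real_, p, a, b)
}

result_row <- function(method, alternative, statistic, df, p, a, b) {
  tibble::tibble(
    method = method, alternative = alternative,
    statistic = statistic, df = df, p_value = p,
    n_a = length(a), n_b = length(b)
  )
}

#' Printed summary table of the 14 placozoan mitogenomes
#'
#' The published per-haplotype summary of placozoan mitochondrial genomes
#' (Polyplacotoma, Trichoplax and Hoilungia lineages): whole-genome,
#' coding-region and intergenic-region sizes and GC percentages, intron
#' class totals, and small-inverted-repeat / tandem-repeat statistics.
#' Bundled as a plain-text fixture so cohort statistics can be reproduced
#' without any downloads.
#'
#' @return A tibble with one row per haplotype.
#' @examples
#' cohort_stats(placozoan_summary()[, c("size_bp", "gc_pct")])
#' @export
placozoan_summary <- function() {
  path <- system.file("extdata", "placozoa_table1.tsv", package = "mitosir",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
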
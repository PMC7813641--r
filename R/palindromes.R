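#' Parameters for the small-inverted-repeat scan
#'
#' Defaults follow the classic hairpin-scan settings used for animal
#' mitogenomes: stems (arms) of 6 to 100 bp, a loop (gap) of at most 10 bp,
#' at most one mismatched base pair, and the selection rule that the stem
#' must be longer than the loop.
#'
#' @param min_stem,max_stem Minimum/maximum arm length in bp.
#' @param max_loop Maximum loop (gap between arms) in bp.
#' @param max_mismatch Maximum number of mismatched base pairs in the stem.
#' @param require_stem_gt_loop Apply the stem > loop selection downstream.
#' @return A validated list of class `palindrome_params`.
#' @export
palindrome_params <- function(min_stem = 6L, max_stem = 100L, max_loop = 10L,
                              max_mismatch = 1L, require_stem_gt_loop = TRUE) {
  p <- list(
    min_stem = as.integer(min_stem), max_stem = as.integer(max_stem),
    max_loop = as.integer(max_loop), max_mismatch = as.integer(max_mismatch),
    require_stem_gt_loop = isTRUE(require_stem_gt_loop)
  )
  stopifnot(p$min_stem >= 1L, p$min_stem <= p$max_stem,
            p$max_loop >= 0L, p$max_mismatch >= 0L)
  structure(p, class = "palindrome_params")
}

dna_to_int <- function(seq_chr) {
  code <- rep(4L, 256L)
  code[utf8ToInt("A")] <- 0L
  code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L
  code[utf8ToInt("T")] <- 3L
  code[utf8ToInt(seq_chr)]
}

#' Find maximal small inverted repeats
#'
#' Scans a genome for inverted repeats (hairpins): two reverse-complementary
#' arms of equal length separated by a loop, with at most
#' `params$max_mismatch` mismatched base pairs. Every reported hit is
#' maximal: neither growing both arms outward nor growing them into the
#' loop keeps the hit within the mismatch budget, the arm-length cap and
#' (for circular genomes) the genome span. Circular genomes are scanned
#' across the origin; coordinates of origin-crossing hits are reported on
#' the unrolled circle (positions past the genome length wrap).
#'
#' @param genome A [circular_genome()] or a DNA string (treated as linear).
#' @param params A [palindrome_params()] object.
#' @return A tibble with one row per maximal hit: `genome_id`,
#'   `left_start`, `left_end`, `right_start`, `right_end` (0-based
#'   half-open), `stem_len`, `loop_len`, `mismatches`, `hexamer` (the six
#'   loop-adjacent bases of the left arm). Sorted by left-arm start, then
#'   stem length descending. The stem > loop selection is *not* applied
#'   here; see [filter_stem_gt_loop()].
#' @examples
#' find_palindromes("AGGCGCCTTTGGCGCCA", palindrome_params(max_mismatch = 0))
#' @export
find_palindromes <- function(genome, params = palindrome_params()) {
  if (is.character(genome)) genome <- circular_genome(genome, topology = "linear")
  stopifnot(inherits(genome, "circular_genome"), inherits(params, "palindrome_params"))
  n <- genome_length(genome)
  s <- genome$sequence

  if (is_circular(genome) && n >= 2L) {
    max_span <- min(n, 2L * params$max_stem + params$max_loop)
    ext_len <- n + max_span + 2L
    reps <- ceiling(ext_len / n) + 1L
    ext <- substr(strrep(s, reps), 1L, ext_len)
    raw <- scan_palindromes_cpp(
      dna_to_int(ext), params$min_stem, params$max_stem, params$max_loop,
      params$max_mismatch, 1L, n, max_span
    )
    shift <- ifelse(raw$left_start == n, n, 0L)
    raw$left_start <- raw$left_start - shift
  } else {
    raw <- scan_palindromes_cpp(
      dna_to_int(s), params$min_stem, params$max_stem, params$max_loop,
      params$max_mismatch, 0L, n, 2L * params$max_stem + params$max_loop
    )
  }

  hits <- tibble::tibble(
    genome_id = genome$id,
    left_start = as.integer(raw$left_start),
    left_end = as.integer(raw$left_start + raw$stem_len),
    right_start = as.integer(raw$left_start + raw$stem_len + raw$loop_len),
    right_end = as.integer(raw$left_start + 2L * raw$stem_len + raw$loop_len),
    stem_len = as.integer(raw$stem_len),
    loop_len = as.integer(raw$loop_len),
    mismatches = as.integer(raw$mismatches)
  )
  hits <- dplyr::arrange(hits, .data$left_start, dplyr::desc(.data$stem_len),
                         .data$loop_len)
  classify_hexamer(hits, genome)
}

#' Keep hits whose stem is longer than the loop
#'
#' The selection rule applied before repeat-type calling: a hit is kept only
#' if `stem_len > loop_len` (strict).
#'
#' @param hits A hit tibble from [find_palindromes()].
#' @return The filtered tibble.
#' @export
filter_stem_gt_loop <- function(hits) {
  dplyr::filter(hits, .data$stem_len > .data$loop_len)
}

#' Classify hits by the six stem nucleotides adjacent to the loop
#'
#' The class label is the last six bases of the left (5') arm read 5' to 3' on
#' the deposited strand. Stems containing `N` in the classifying window get
#' class `"ambiguous"` and are excluded from type tables.
#'
#' @param hits A hit tibble.
#' @param genome The genome the hits were found on.
#' @return `hits` with a `hexamer` column added/updated.
#' @export
classify_hexamer <- function(hits, genome) {
  if (is.character(genome)) genome <- circular_genome(genome, topology = "linear")
  n <- genome_length(genome)
  b <- strsplit(genome$sequence, "")[[1]]
  hex <- vapply(seq_len(nrow(hits)), function(i) {
    if (hits$stem_len[i] < 6L) return(NA_character_)
    pos <- (seq.int(hits$left_end[i] - 6L, hits$left_end[i] - 1L) %% n) + 1L
    h <- paste(b[pos], collapse = "")
    if (grepl("N", h, fixed = TRUE)) "ambiguous" else h
  }, character(1))
  hits$hexamer <- hex
  hits
}

#' Call repeat-level hexamer types
#'
#' Hexamer classes observed at least `threshold` times in a single genome
#' are called "repeat" types (SIR families). Hits must come from one genome
#' and should already be stem > loop filtered.
#'
#' @param hits A filtered, classified hit tibble from one genome.
#' @param threshold Minimum per-genome count (default 10).
#' @return A tibble `hexamer`, `n` of called types, count-descending.
#' @export
call_repeat_types <- function(hits, threshold = 10L) {
  hits |>
    dplyr::filter(!is.na(.data$hexamer), .data$hexamer != "ambiguous") |>
    dplyr::count(.data$hexamer, name = "n") |>
    dplyr::filter(.data$n >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$hexamer)
}

#' Assign each hit to a genome region
#'
#' A hit is `coding` if its full span (arms plus loop) lies in coding
#' sequence, `intergenic` if it lies fully outside, and `spanning`
#' otherwise; the `midpoint_class` column gives the two-way class used for
#' coding/intergenic tallies of spanning hits.
#'
#' @param hits A hit tibble (or any tibble with `left_start`/`right_end`, or
#'   `start`/`end` columns).
#' @param partition A [partition_regions()] result for the same genome.
#' @return `hits` with `region` and `midpoint_class` columns.
#' @export
assign_regions <- function(hits, partition) {
  if (nrow(hits) == 0L) {
    hits$region <- character(0)
    hits$midpoint_class <- character(0)
    return(hits)
  }
  start <- if ("left_start" %in% names(hits)) hits$left_start else hits$start
  end <- if ("right_end" %in% names(hits)) hits$right_end else hits$end
  rg <- region_of_span(partition, start, end)
  hits$region <- rg$region
  hits$midpoint_class <- rg$midpoint_class
  hits
}

#' One-call SIR scan of a genome
#'
#' Runs [find_palindromes()], applies the stem > loop selection, assigns
#' regions when a partition is supplied, and calls repeat types.
#'
#' @inheritParams find_palindromes
#' @param partition Optional [partition_regions()] result.
#' @param threshold Repeat-type threshold (default 10).
#' @return A list with `hits` (filtered, classified, region-assigned) and
#'   `roster` (called repeat types with counts).
#' @export
scan_sirs <- function(genome, params = palindrome_params(), partition = NULL,
                      threshold = 10L) {
  hits <- find_palindromes(genome, params)
  if (params$require_stem_gt_loop) hits <- filter_stem_gt_loop(hits)
  if (!is.null(partition)) hits <- assign_regions(hits, partition)
  list(hits = hits, roster = call_repeat_types(hits, threshold))
}

#' Tabulate SIR statistics across a cohort
#'
#' Builds per-genome counts per hexamer class restricted to the repeat-type
#' roster, with per-region counts and total bp. With
#' `roster_scope = "union"` the roster pools types called repeat-level in
#' any analyzed genome (a class kept once it reaches the threshold
#' anywhere); with `"per_genome"` each genome's own roster is used.
#' Hits spanning a region boundary are tallied to the class holding their
#' midpoint for the two-way coding/intergenic split.
#'
#' @param hits A classified hit tibble with a `genome_id` column covering
#'   the cohort (post stem > loop filter), or a named list of per-genome hit
#'   tibbles.
#' @param partitions Named list of [partition_regions()] results (names =
#'   genome ids); genomes without a partition get total-only statistics.
#' @param threshold Repeat-type threshold (default 10).
#' @param roster_scope `"union"` or `"per_genome"`.
#' @return An object of class `sir_table`: list with `counts` (genome x
#'   class tibble), `totals` (per-genome totals), `roster` and settings.
#' @export
build_sir_tables <- function(hits, partitions = NULL, threshold = 10L,
                             roster_scope = c("union", "per_genome")) {
  roster_scope <- match.arg(roster_scope)
  if (is.list(hits) && !is.data.frame(hits)) hits <- dplyr::bind_rows(hits)
  hits <- filter_stem_gt_loop(hits)
  genomes <- unique(hits$genome_id)

  per_genome_roster <- lapply(genomes, function(g) {
    call_repeat_types(hits[hits$genome_id == g, , drop = FALSE], threshold)$hexamer
  })
  names(per_genome_roster) <- genomes
  union_roster <- sort(unique(unlist(per_genome_roster)))

  counts <- purrr::map_dfr(genomes, function(g) {
    h <- hits[hits$genome_id == g, , drop = FALSE]
    roster <- if (roster_scope == "union") union_roster else per_genome_roster[[g]]
    h <- h[!is.na(h$hexamer) & h$hexamer %in% roster, , drop = FALSE]
    part <- partitions[[g]]
    if (is.null(part)) {
      if (!is.null(partitions)) {
        rlang::inform(paste0("no region partition for ", g,
                             "; reporting total-only SIR statistics"))
      }
      h$midpoint_class <- NA_character_
    } else if (!"midpoint_class" %in% names(h)) {
      h <- assign_regions(h, part)
    }
    h$span_bp <- h$right_end - h$left_start
    got <- h |>
      dplyr::group_by(hexamer = .data$hexamer) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_cr = sum(.data$midpoint_class == "coding"),
        n_igr = sum(.data$midpoint_class == "intergenic"),
        bp = sum(.data$span_bp),
        bp_cr = sum(.data$span_bp[.data$midpoint_class == "coding"]),
        bp_igr = sum(.data$span_bp[.data$midpoint_class == "intergenic"]),
        .groups = "drop"
      )
    out <- tibble::tibble(genome_id = g, hexamer = roster) |>
      dplyr::left_join(got, by = "hexamer")
    out[is.na(out$n), c("n", "n_cr", "n_igr", "bp", "bp_cr", "bp_igr")] <- 0L
    out
  })

  totals <- counts |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(
      n_total = sum(.data$n), n_cr = sum(.data$n_cr), n_igr = sum(.data$n_igr),
      bp_total = sum(.data$bp), bp_cr = sum(.data$bp_cr), bp_igr = sum(.data$bp_igr),
      .groups = "drop"
    )

  structure(
    list(counts = counts, totals = totals,
         roster = union_roster, per_genome_roster = per_genome_roster,
         threshold = as.integer(threshold), roster_scope = roster_scope),
    class = "sir_table"
  )
}

#' @export
print.sir_table <- function(x, ...) {
  cat(sprintf("<sir_table> %d genome(s), %d repeat type(s) [scope: %s, threshold %d]\n",
              nrow(x$totals), length(x$roster), x$roster_scope, x$threshold))
  print(x$totals)
  invisible(x)
}

#' @rdname build_sir_tables
#' @param x A `sir_table`.
#' @param ... Unused.
#' @method tidy sir_table
#' @export
tidy.sir_table <- function(x, ...) x$counts

#' @rdname build_sir_tables
#' @method glance sir_table
#' @export
glance.sir_table <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x$totals),
    n_types = length(x$roster),
    n_hits = sum(x$totals$n_total),
    threshold = x$threshold,
    roster_scope = x$roster_scope
  )
}
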
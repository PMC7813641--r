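#' Run the full cohort analysis
#'
#' Orchestrates the stages over a set of annotated genomes: read, region
#' partition, SIR scan, tandem scan, GC profile, gene-order sections (when
#' at least two genomes are given), and the cohort summary table with
#' mean and population-SD footer rows. Writes TSV/BED outputs and a JSON
#' manifest with parameters and input checksums; the run is deterministic,
#' so rerunning on identical inputs reproduces every output byte for byte.
#'
#' @param genomes A character vector of GenBank file paths, or a named list
#'   of `list(genome =, features =)` bundles.
#' @param out_dir Output directory (created if needed); `NULL` for no file
#'   output.
#' @param sir_params A [palindrome_params()].
#' @param tandem_params_ A [tandem_params()].
#' @param threshold SIR repeat-type threshold.
#' @param gc_window,gc_step GC profile settings.
#' @param tree Optional tree (Newick path/string or `phylo`) for mapping
#'   gene-order changes on edges.
#' @return A list with `summaries`, `cohort`, `sir_table`, `sections`,
#'   `section_orders`, `edge_changes`, `gc_profiles`, `hits`, `tandems`,
#'   and `manifest`, invisibly usable for further analysis.
#' @export
run_cohort <- function(genomes, out_dir = NULL,
                       sir_params = palindrome_params(),
                       tandem_params_ = tandem_params(),
                       threshold = 10L,
                       gc_window = 100L, gc_step = 10L,
                       tree = NULL) {
  bundles <- load_bundles(genomes)
  ids <- names(bundles)
  message("cohort of ", length(bundles), " genome(s): ", paste(ids, collapse = ", "))

  partitions <- list()
  hit_list <- list()
  tandem_list <- list()
  profiles <- list()
  orders <- list()
  summaries <- list()
  for (id in ids) {
    bn <- bundles[[id]]
    message("[", id, "] partitioning and scanning")
    part <- partition_regions(bn$genome, bn$features)
    scan <- scan_sirs(bn$genome, sir_params, part, threshold)
    td <- find_tandem_repeats(bn$genome, tandem_params_)
    if (nrow(td) > 0L) td <- assign_regions(td, part)
    partitions[[id]] <- part
    hit_list[[id]] <- scan$hits
    tandem_list[[id]] <- td
    profiles[[id]] <- gc_profile(bn$genome, gc_window, gc_step)
    orders[[id]] <- extract_gene_order(bn$features, genome_id = id)
    summaries[[id]] <- summarize_genome(bn$genome, part, scan$hits, td)
  }
  summaries <- dplyr::bind_rows(summaries)
  cohort <- cohort_stats(summaries)
  sir_tab <- build_sir_tables(hit_list, partitions, threshold, "union")

  sections <- NULL
  section_orders <- NULL
  edge_changes <- NULL
  if (length(bundles) >= 2L) {
    sections <- merge_sections(orders)
    section_orders <- lapply(ids, function(id) section_order(orders[[id]], sections))
    names(section_orders) <- ids
    if (!is.null(tree)) {
      edge_changes <- map_events_on_tree(section_orders, tree)
    }
  } else {
    message("single genome: gene-order stage skipped")
  }

  manifest <- list(
    package = "mitosir",
    version = as.character(utils::packageVersion("mitosir")),
    genomes = ids,
    parameters = list(
      sir = unclass(sir_params),
      tandem = unclass(tandem_params_),
      threshold = threshold,
      gc_window = gc_window, gc_step = gc_step
    ),
    input_checksums = if (is.character(genomes)) {
      as.list(tools::md5sum(genomes))
    } else {
      lapply(bundles, function(bn) unname(tools::md5sum(
        textConnection_md5(bn$genome$sequence))))
    }
  )

  result <- list(
    summaries = summaries, cohort = cohort, sir_table = sir_tab,
    sections = sections, section_orders = section_orders,
    edge_changes = edge_changes, gc_profiles = profiles,
    hits = hit_list, tandems = tandem_list, partitions = partitions,
    manifest = manifest
  )
  if (!is.null(out_dir)) write_cohort_outputs(result, out_dir)
  invisible(result)
}

# md5 of an in-memory sequence without temp-file churn
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(x, tf)
  tf
}

load_bundles <- function(genomes) {
  if (is.character(genomes)) {
    bundles <- lapply(genomes, read_genbank)
    names(bundles) <- vapply(bundles, function(bn) bn$genome$id, character(1))
    return(bundles)
  }
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  nm <- names(genomes)
  if (is.null(nm)) {
    nm <- vapply(genomes, function(bn) bn$genome$id, character(1))
  }
  names(genomes) <- nm
  genomes
}

write_cohort_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # Table-1-style summary with Average / S.D. footer rows
  summ <- result$summaries
  num <- vapply(summ, is.numeric, logical(1))
  footer <- function(fun, label) {
    row <- summ[1, ]
    row$genome_id <- label
    for (cl in names(summ)[num]) row[[cl]] <- fun(summ[[cl]])
    row
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tab <- dplyr::bind_rows(summ, footer(mean, "Average"), footer(pop_sd, "S.D."))
  readr::write_tsv(tab, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(result$sir_table$counts, file.path(out_dir, "sir_counts.tsv"))
  readr::write_tsv(result$sir_table$totals, file.path(out_dir, "sir_totals.tsv"))
  for (id in names(result$hits)) {
    h <- result$hits[[id]]
    if (nrow(h) > 0L) {
      bed <- tibble::tibble(start = h$left_start, end = h$right_end,
                            name = h$hexamer, score = h$stem_len,
                            strand = "+")
      write_bed(bed, file.path(out_dir, paste0(id, "_sirs.bed")), chrom = id)
    }
    readr::write_tsv(result$tandems[[id]],
                     file.path(out_dir, paste0(id, "_tandem.tsv")))
    readr::write_tsv(tibble::as_tibble(result$gc_profiles[[id]]),
                     file.path(out_dir, paste0(id, "_gc.tsv")))
  }
  if (!is.null(result$sections)) {
    readr::write_tsv(result$sections$sections, file.path(out_dir, "sections.tsv"))
    so <- purrr::map_dfr(names(result$section_orders), function(id) {
      x <- result$section_orders[[id]]
      tibble::tibble(genome_id = id, position = x$position,
                     section = x$section, orientation = x$orientation)
    })
    readr::write_tsv(so, file.path(out_dir, "section_orders.tsv"))
  }
  if (!is.null(result$edge_changes)) {
    ec <- result$edge_changes
    ec$gained <- vapply(ec$gained, paste, character(1), collapse = ";")
    ec$lost <- vapply(ec$lost, paste, character(1), collapse = ";")
    readr::write_tsv(ec, file.path(out_dir, "edge_changes.tsv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
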
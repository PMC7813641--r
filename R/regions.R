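#' Partition a genome into coding, intergenic and intron regions
#'
#' Coding is the union of exonic spans of protein genes, rRNA fragments,
#' tRNAs and annotated ORFs. Annotated group I / group II intron spans are
#' reported as their own classes but are counted inside the intergenic
#' total, so that coding + intergenic always equals the genome length.
#' Overlaps are resolved with precedence coding > intron > intergenic.
#'
#' @param genome A [circular_genome()].
#' @param feats A [features()] tibble (may be empty).
#' @return An object of class `region_partition`: a list with
#'   `intervals` (tibble of `class`, `start`, `end`), `sizes` and `gc`
#'   (named numeric vectors over `coding`, `intergenic`, `intronI`,
#'   `intronII`), `counts` (merged-interval counts for the intron classes),
#'   `coding_mask` (logical per base) and `genome_id`.
#' @examples
#' g <- circular_genome(strrep("ACGT", 250), "toy")
#' f <- features("geneA", "protein_gene", 100, 400)
#' p <- partition_regions(g, f)
#' p$sizes
#' @export
partition_regions <- function(genome, feats) {
  n <- genome_length(genome)
  feats <- validate_features(feats, n)

  ir_of <- function(kinds) {
    rows <- feats[feats$kind %in% kinds, , drop = FALSE]
    if (nrow(rows) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = rows$start + 1L, end = rows$end))
  }
  coding <- ir_of(coding_kinds)
  intron1 <- ir_of("intron_groupI")
  intron2 <- ir_of("intron_groupII")

  overlap1 <- IRanges::intersect(intron1, coding)
  overlap2 <- IRanges::intersect(intron2, coding)
  if (sum(IRanges::width(overlap1)) + sum(IRanges::width(overlap2)) > 0L) {
    rlang::inform(paste0(
      "intron annotation overlaps coding features in ", genome$id,
      "; coding takes precedence over the overlapping bases"
    ))
    intron1 <- IRanges::setdiff(intron1, coding)
    intron2 <- IRanges::setdiff(intron2, coding)
  }
  whole <- IRanges::IRanges(start = 1L, end = n)
  intergenic <- IRanges::setdiff(whole, coding)

  bases <- strsplit(genome$sequence, "")[[1]]
  coding_mask <- rep(FALSE, n)
  if (length(coding) > 0L) {
    coding_mask[unlist(Map(seq, IRanges::start(coding), IRanges::end(coding)))] <- TRUE
  }
  gc_of <- function(ir) {
    if (length(ir) == 0L || sum(IRanges::width(ir)) == 0L) return(NA_real_)
    idx <- unlist(Map(seq, IRanges::start(ir), IRanges::end(ir)))
    gc_fraction(paste(bases[idx], collapse = ""))
  }

  ir_tbl <- function(ir, class) {
    tibble::tibble(class = class,
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  }
  intervals <- dplyr::bind_rows(
    ir_tbl(coding, "coding"),
    ir_tbl(intergenic, "intergenic"),
    ir_tbl(intron1, "intronI"),
    ir_tbl(intron2, "intronII")
  )

  sizes <- c(
    coding = sum(IRanges::width(coding)),
    intergenic = n - sum(IRanges::width(coding)),
    intronI = sum(IRanges::width(intron1)),
    intronII = sum(IRanges::width(intron2))
  )
  structure(
    list(
      intervals = intervals,
      sizes = sizes,
      gc = c(coding = gc_of(coding), intergenic = gc_of(intergenic),
             intronI = gc_of(intron1), intronII = gc_of(intron2)),
      counts = c(intronI = length(intron1), intronII = length(intron2)),
      coding_mask = coding_mask,
      genome_length = n,
      genome_id = genome$id
    ),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %s (%s bp)\n", x$genome_id,
              format(x$genome_length, big.mark = ",")))
  for (cl in names(x$sizes)) {
    cat(sprintf("  %-10s %8d bp  GC %s\n", cl, x$sizes[[cl]],
                ifelse(is.na(x$gc[[cl]]), "NA",
                       sprintf("%.2f%%", 100 * x$gc[[cl]]))))
  }
  invisible(x)
}

#' @rdname partition_regions
#' @param x A `region_partition`.
#' @param ... Unused.
#' @method tidy region_partition
#' @export
tidy.region_partition <- function(x, ...) {
  x$intervals
}

# Region class of a span [start, end) on the unrolled circle: "coding" if
# every base is coding, "intergenic" if none is, else "spanning". The
# midpoint class is used for two-way tallies of spanning elements.
region_of_span <- function(partition, start, end) {
  n <- partition$genome_length
  mask <- partition$coding_mask
  k <- length(start)
  region <- character(k)
  midpoint_class <- character(k)
  for (i in seq_len(k)) {
    pos <- (seq.int(start[i], end[i] - 1L) %% n) + 1L
    inside <- mask[pos]
    region[i] <- if (all(inside)) "coding" else if (!any(inside)) "intergenic" else "spanning"
    mid <- pos[ceiling(length(pos) / 2)]
    midpoint_class[i] <- if (mask[mid]) "coding" else "intergenic"
  }
  tibble::tibble(region = region, midpoint_class = midpoint_class)
}

#' Extract the signed circular gene order from a feature table
#'
#' Features of the dropped kinds (by default ORFs of unknown function and
#' introns) are excluded; every remaining annotated fragment contributes one
#' unit (e.g. `16Sa` and `16Sb` are separate units). Units are listed in
#' genomic order of their first part. Duplicate labels are suffixed
#' deterministically (`label_1`, `label_2`) in genomic order.
#'
#' @param feats A [features()] tibble.
#' @param drop_kinds Feature kinds excluded from the order.
#' @param genome_id Identifier attached to the resulting order.
#' @return A tibble of class `gene_order` with columns `position`, `label`,
#'   `strand`, carrying a `genome_id` attribute. The order is cyclic:
#'   rotations (and full reflection with sign flip) denote the same
#'   arrangement.
#' @export
extract_gene_order <- function(feats,
                               drop_kinds = c("orf_unknown", "intron_groupI",
                                              "intron_groupII"),
                               genome_id = "genome") {
  feats <- feats[!feats$kind %in% drop_kinds, , drop = FALSE]
  if (nrow(feats) == 0L) {
    return(new_gene_order(tibble::tibble(position = integer(),
                                         label = character(),
                                         strand = character()),
                          genome_id))
  }
  units <- feats |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      label = .data$label[1],
      strand = .data$strand[1],
      at = min(.data$start),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$at)
  dup <- units$label[duplicated(units$label)]
  if (length(dup) > 0L) {
    rlang::inform(paste0("duplicate gene labels suffixed in genomic order: ",
                         paste(unique(dup), collapse = ", ")))
    for (lab in unique(units$label)) {
      idx <- which(units$label == lab)
      if (length(idx) > 1L) {
        units$label[idx] <- paste0(lab, "_", seq_along(idx))
      }
    }
  }
  new_gene_order(
    tibble::tibble(position = seq_len(nrow(units)),
                   label = units$label, strand = units$strand),
    genome_id
  )
}

new_gene_order <- function(tbl, genome_id) {
  attr(tbl, "genome_id") <- genome_id
  class(tbl) <- unique(c("gene_order", class(tbl)))
  tbl
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d units (cyclic)\n",
              attr(x, "genome_id") %||% "?", nrow(x)))
  if (nrow(x) > 0L) {
    cat(" ", paste0(ifelse(x$strand == "+", "+", "-"), x$label, collapse = " "), "\n")
  }
  invisible(x)
}

#' Write per-class region sizes and GC as a TSV
#' @param partition A `region_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  tbl <- tibble::tibble(
    genome_id = partition$genome_id,
    class = names(partition$sizes),
    size_bp = as.integer(partition$sizes),
    gc_pct = round(100 * partition$gc[names(partition$sizes)], 2)
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}
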
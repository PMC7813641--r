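#' Build a feature table
#'
#' Features are typed, stranded intervals on a genome, held as a tibble with
#' one row per interval part. Coordinates are 0-based half-open
#' (BED-compatible); GenBank I/O converts from/to the 1-based inclusive
#' convention. A feature that wraps the origin of a circular genome is
#' represented as two parts of one `feature_id`; parts are ordered along the
#' transcription direction.
#'
#' @param label Feature/fragment name (e.g. `cox1_e3`, `16Sb`, `trnR`).
#' @param kind One of `protein_gene`, `rRNA`, `tRNA`, `orf_unknown`,
#'   `intron_groupI`, `intron_groupII`, `exon`, `other`.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"`.
#' @param feature_id Integer grouping of parts into features; defaults to one
#'   feature per row.
#' @param part Part index along transcription direction (default 1).
#' @return A tibble of class `mito_features`.
#' @export
features <- function(label, kind, start, end, strand = "+",
                     feature_id = seq_along(label), part = 1L) {
  tbl <- tibble::tibble(
    feature_id = as.integer(feature_id),
    label = as.character(label),
    kind = as.character(kind),
    strand = as.character(strand),
    start = as.integer(start),
    end = as.integer(end),
    part = as.integer(part)
  )
  validate_features(tbl)
}

feature_kinds <- c(
  "protein_gene", "rRNA", "tRNA", "orf_unknown",
  "intron_groupI", "intron_groupII", "exon", "other"
)

coding_kinds <- c("protein_gene", "rRNA", "tRNA", "orf_unknown", "exon")

validate_features <- function(tbl, genome_len = NULL) {
  needed <- c("feature_id", "label", "kind", "strand", "start", "end", "part")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0L) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) > 0L) {
    if (any(!tbl$kind %in% feature_kinds)) {
      stop("unknown feature kind(s): ",
           paste(unique(setdiff(tbl$kind, feature_kinds)), collapse = ", "),
           call. = FALSE)
    }
    if (any(!tbl$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
    if (any(tbl$end <= tbl$start)) stop("features must have end > start", call. = FALSE)
    if (!is.null(genome_len) && any(tbl$start < 0L | tbl$end > genome_len)) {
      stop("feature interval outside [0, genome length)", call. = FALSE)
    }
  }
  class(tbl) <- unique(c("mito_features", class(tbl)))
  tbl
}

empty_features <- function() {
  features(character(), character(), integer(), integer(),
           strand = character(), feature_id = integer(), part = integer())
}

# ---- GenBank flat-file I/O ------------------------------------------------
# Minimal flat-file dialect: LOCUS topology, a feature table with the keys
# used below, and an ORIGIN sequence block. Written records round-trip
# bit-identically through read_genbank().

kind_to_gb_key <- c(
  protein_gene = "CDS", orf_unknown = "CDS", rRNA = "rRNA", tRNA = "tRNA",
  intron_groupI = "intron", intron_groupII = "intron",
  exon = "exon", other = "misc_feature"
)

#' Read a GenBank flat file
#'
#' Parses the LOCUS topology, the feature table and the ORIGIN sequence of a
#' single-record GenBank flat file. `join`/`complement` locations are
#' resolved into multi-part stranded features in 0-based half-open
#' coordinates, with parts ordered along the transcription direction;
#' origin-wrapping locations on circular genomes become two parts of one
#' feature. Unparseable features are skipped with a warning; a missing
#' sequence is an error.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with elements `genome` (a [circular_genome()]) and
#'   `features` (a [features()] tibble).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  topology <- if (grepl("circular", locus[1], ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])), "\\s+")[[1]][1]

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) stop("GenBank record has no ORIGIN sequence: ", path, call. = FALSE)
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at) > 0L) end_at[end_at > origin_at[1]][1] else length(lines) + 1L
  seq_lines <- if (origin_at[1] + 1L <= end_at - 1L) {
    lines[seq(origin_at[1] + 1L, end_at - 1L)]
  } else {
    character()
  }
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has an empty sequence: ", path, call. = FALSE)

  feats_at <- grep("^FEATURES", lines)
  feature_rows <- list()
  if (length(feats_at) > 0L) {
    block <- lines[seq(feats_at[1] + 1L, origin_at[1] - 1L)]
    entries <- split_gb_entries(block)
    fid <- 0L
    for (entry in entries) {
      key <- entry$key
      if (key %in% c("source", "gene")) next
      parsed <- tryCatch(
        parse_gb_entry(key, entry$location, entry$qualifiers, nchar(sequence)),
        error = function(e) {
          warning("skipping unparseable ", key, " feature (", conditionMessage(e), ")",
                  call. = FALSE)
          NULL
        }
      )
      if (is.null(parsed)) next
      fid <- fid + 1L
      parsed$feature_id <- fid
      feature_rows[[fid]] <- parsed
    }
  }
  feats <- if (length(feature_rows) > 0L) {
    validate_features(dplyr::bind_rows(feature_rows), nchar(sequence))
  } else {
    empty_features()
  }
  list(
    genome = circular_genome(sequence, id = id, topology = topology),
    features = feats
  )
}

# Split the FEATURES block into entries: a new entry starts with a key in
# column 6; all other lines (location continuations, qualifiers) belong to
# the current entry.
split_gb_entries <- function(block) {
  is_key <- grepl("^ {5}\\S", block)
  idx <- cumsum(is_key)
  out <- list()
  for (grp in split(block, idx)[as.character(seq_len(max(idx, 0)))]) {
    first <- grp[1]
    key <- sub("^\\s*(\\S+).*$", "\\1", first)
    rest <- trimws(sub("^\\s*\\S+\\s*", "", first))
    more <- if (length(grp) > 1L) trimws(grp[-1]) else character()
    qual_start <- which(grepl("^/", more))[1]
    if (is.na(qual_start)) {
      location <- paste0(rest, paste(more, collapse = ""))
      quals <- character()
    } else {
      location <- paste0(rest, paste(more[seq_len(qual_start - 1L)], collapse = ""))
      quals <- more[seq(qual_start, length(more))]
    }
    out[[length(out) + 1L]] <- list(key = key, location = location, qualifiers = quals)
  }
  out
}

gb_qualifier <- function(qualifiers, name) {
  hits <- grep(paste0("^/", name, "="), qualifiers, value = TRUE)
  if (length(hits) == 0L) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hits[1]))
}

parse_gb_entry <- function(key, location, qualifiers, genome_len) {
  loc <- parse_gb_location(location)
  note <- gb_qualifier(qualifiers, "note")
  product <- gb_qualifier(qualifiers, "product")
  label <- gb_qualifier(qualifiers, "gene")
  if (is.na(label)) label <- gb_qualifier(qualifiers, "label")
  if (is.na(label)) label <- product
  if (is.na(label)) label <- note
  if (is.na(label)) label <- key
  kind <- switch(key,
    CDS = if (!is.na(note) && grepl("unknown|hypothetical", note, ignore.case = TRUE)) {
      "orf_unknown"
    } else if (!is.na(product) && grepl("hypothetical", product, ignore.case = TRUE)) {
      "orf_unknown"
    } else {
      "protein_gene"
    },
    rRNA = "rRNA",
    tRNA = "tRNA",
    intron = if (!is.na(note) && grepl("group\\s*II", note, ignore.case = TRUE)) {
      "intron_groupII"
    } else if (!is.na(note) && grepl("group\\s*I", note, ignore.case = TRUE)) {
      "intron_groupI"
    } else {
      "other"
    },
    exon = "exon",
    "other"
  )
  if (any(loc$start < 0L) || any(loc$end > genome_len)) {
    stop("location outside sequence bounds")
  }
  tibble::tibble(
    feature_id = NA_integer_,
    label = label,
    kind = kind,
    strand = loc$strand,
    start = loc$start,
    end = loc$end,
    part = seq_len(nrow(loc))
  )
}

# Parse a GenBank location string into 0-based half-open parts ordered along
# the transcription direction. Supports s..e, single bases, join()/order(),
# complement() outside or around individual segments, and <,> partial marks.
parse_gb_location <- function(location) {
  loc <- gsub("\\s", "", location)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  elems <- strsplit(loc, ",")[[1]]
  if (length(elems) == 0L) stop("empty location")
  inner_comp <- grepl("^complement\\(", elems)
  if (any(inner_comp)) {
    if (!all(inner_comp) || strand == "-") stop("mixed-strand location not supported")
    strand <- "-"
    elems <- sub("^complement\\(", "", elems)
    elems <- sub("\\)$", "", elems)
    listed_in_transcription_order <- TRUE
  } else {
    listed_in_transcription_order <- (strand == "+")
  }
  elems <- gsub("[<>]", "", elems)
  parse_one <- function(e) {
    if (grepl("^\\d+$", e)) {
      p <- as.integer(e)
      c(p - 1L, p)
    } else if (grepl("^\\d+\\.\\.\\d+$", e)) {
      se <- as.integer(strsplit(e, "\\.\\.")[[1]])
      if (se[2] < se[1]) stop("end before start in location element: ", e)
      c(se[1] - 1L, se[2])
    } else {
      stop("cannot parse location element: ", e)
    }
  }
  mat <- unname(t(vapply(elems, parse_one, integer(2))))
  if (!listed_in_transcription_order) mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  tibble::tibble(start = mat[, 1], end = mat[, 2], strand = strand)
}

format_gb_location <- function(parts, strand) {
  # parts in transcription order; emit genomic order, complement() for minus
  segs <- sprintf("%d..%d", parts$start + 1L, parts$end)
  if (strand == "-") segs <- rev(segs)
  body <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")") else segs
  if (strand == "-") paste0("complement(", body, ")") else body
}

#' Write a genome and its features as a GenBank flat file
#'
#' Emits a minimal GenBank record (LOCUS with topology, feature table,
#' ORIGIN) that [read_genbank()] parses back to an identical genome and
#' feature table. The LOCUS date field is fixed so reruns are byte-identical.
#'
#' @param genome A [circular_genome()].
#' @param feats A [features()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, feats, path) {
  n <- genome_length(genome)
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s UNA 01-JAN-2026",
            genome$id, n, genome$topology),
    sprintf("DEFINITION  %s.", genome$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", n))
  )
  if (nrow(feats) > 0L) {
    for (fid in unique(feats$feature_id)) {
      f <- feats[feats$feature_id == fid, , drop = FALSE]
      f <- f[order(f$part), , drop = FALSE]
      key <- kind_to_gb_key[[f$kind[1]]]
      out <- c(out, sprintf("     %-16s%s", key,
                            format_gb_location(f, f$strand[1])))
      out <- c(out, sprintf("                     /gene=\"%s\"", f$label[1]))
      note <- switch(f$kind[1],
        orf_unknown = "ORF of unknown function",
        intron_groupI = "group I intron",
        intron_groupII = "group II intron",
        NULL
      )
      if (!is.null(note)) {
        out <- c(out, sprintf("                     /note=\"%s\"", note))
      }
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as a BED file
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates are written as stored. Wrapped intervals (end past the genome
#' length) are written on the unrolled circle.
#'
#' @param x A tibble with `start` and `end` columns; optional `name`/`label`,
#'   `score` and `strand` columns are carried through.
#' @param path Output path.
#' @param chrom Chromosome/genome name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom = "genome") {
  name <- if ("name" %in% names(x)) x$name else if ("label" %in% names(x)) x$label else "."
  score <- if ("score" %in% names(x)) x$score else 0L
  strand <- if ("strand" %in% names(x)) x$strand else "."
  bed <- tibble::tibble(
    chrom = chrom, start = x$start, end = x$end,
    name = name, score = score, strand = strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
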
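# Synthetic annotated mitogenome generator: circular genomes with a
# placozoan-like gene complement, planted hairpin (SIR) families and tandem
# arrays with truth coordinates, and inversion/translocation events applied
# along a phylogeny.

#' Placozoan-like gene layout template
#'
#' Default gene complement used by [generate_genome()]: 12 protein-coding
#' genes (cox1 and nad5 fragmented by introns), a fragmented large rRNA,
#' 12S rRNA, 24 tRNAs, one ORF of unknown function and three introns.
#'
#' @return A tibble with columns `label`, `kind`, `length`, `strand`, in
#'   circle order.
#' @export
placozoan_gene_template <- function() {
  t_rna <- function(aa) tibble::tibble(label = paste0("trn", aa), kind = "tRNA",
                                       length = 70L, strand = "+")
  dplyr::bind_rows(
    tibble::tibble(label = "16Sa", kind = "rRNA", length = 800L, strand = "+"),
    t_rna("M"),
    tibble::tibble(label = "nad5_e1", kind = "protein_gene", length = 1000L, strand = "+"),
    tibble::tibble(label = "nad5_i1", kind = "intron_groupI", length = 600L, strand = "+"),
    tibble::tibble(label = "nad5_e2", kind = "protein_gene", length = 800L, strand = "+"),
    t_rna("W"), t_rna("A"), t_rna("C"),
    tibble::tibble(label = "cox1_e1", kind = "protein_gene", length = 500L, strand = "+"),
    tibble::tibble(label = "cox1_i1", kind = "intron_groupI", length = 700L, strand = "+"),
    tibble::tibble(label = "cox1_e2", kind = "protein_gene", length = 700L, strand = "+"),
    tibble::tibble(label = "cox1_i2", kind = "intron_groupII", length = 400L, strand = "+"),
    tibble::tibble(label = "cox1_e3", kind = "protein_gene", length = 400L, strand = "+"),
    t_rna("D"), t_rna("E"),
    tibble::tibble(label = "cox2", kind = "protein_gene", length = 700L, strand = "+"),
    t_rna("K"), t_rna("F"),
    tibble::tibble(label = "atp6", kind = "protein_gene", length = 700L, strand = "+"),
    tibble::tibble(label = "16Sb", kind = "rRNA", length = 900L, strand = "+"),
    t_rna("R"), t_rna("G"),
    tibble::tibble(label = "cox3", kind = "protein_gene", length = 780L, strand = "+"),
    t_rna("S1"), t_rna("I"),
    tibble::tibble(label = "nad2", kind = "protein_gene", length = 1000L, strand = "-"),
    t_rna("N"), t_rna("L1"),
    tibble::tibble(label = "nad3", kind = "protein_gene", length = 350L, strand = "+"),
    tibble::tibble(label = "nad4", kind = "protein_gene", length = 1350L, strand = "+"),
    t_rna("H"), t_rna("L2"),
    tibble::tibble(label = "nad4L", kind = "protein_gene", length = 300L, strand = "+"),
    tibble::tibble(label = "12S", kind = "rRNA", length = 900L, strand = "+"),
    t_rna("P"), t_rna("Q"),
    tibble::tibble(label = "nad6", kind = "protein_gene", length = 500L, strand = "-"),
    t_rna("T"), t_rna("S2"),
    tibble::tibble(label = "cob", kind = "protein_gene", length = 1140L, strand = "+"),
    t_rna("V"), t_rna("Y"),
    tibble::tibble(label = "nad1", kind = "protein_gene", length = 900L, strand = "+"),
    tibble::tibble(label = "orf1", kind = "orf_unknown", length = 400L, strand = "+")
  )
}

#' Default plans for planted repeat families
#'
#' The default hairpin plan plants GC-rich (`GGCGCC`, `GGATCC`) and AT-rich
#' (`AAAAAA`) stem families at repeat-type abundance (>= 10 copies each),
#' stems 6-10 bp, loops 0-3 bp, one mismatched pair per hairpin (so each
#' plant consumes the scan's mismatch budget and is recovered at its exact
#' coordinates). The tandem plan plants three arrays with periods 12-90 bp.
#'
#' @name synth_plans
#' @return Tibbles describing the planted elements.
#' @export
default_sir_plan <- function() {
  tibble::tibble(
    hexamer = c("GGCGCC", "GGATCC", "AAAAAA"),
    count = c(12L, 10L, 10L),
    stem_min = 6L, stem_max = 10L,
    loop_min = 0L, loop_max = 3L,
    mismatch = 1L,
    region = "intergenic"
  )
}

#' @rdname synth_plans
#' @export
default_tandem_plan <- function() {
  tibble::tibble(
    period = c(12L, 30L, 90L),
    copies = c(8L, 5L, 3L),
    identity = c(1, 1, 0.97)
  )
}

#' Configuration for the synthetic genome generator
#'
#' @param length Genome length in bp (default 36,000, a typical placozoan
#'   mitogenome size).
#' @param gc Background GC fraction (default 0.41, the cohort mean).
#' @param genes Gene layout template (see [placozoan_gene_template()]).
#' @param sir_plan Planted hairpin plan (see [default_sir_plan()]).
#' @param tandem_plan Planted tandem-array plan.
#' @param min_spacing Minimum distance in bp between planted elements
#'   (default 150, so planted hits can never interact or merge).
#' @param id Genome identifier.
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(length = 36000L, gc = 0.41,
                         genes = placozoan_gene_template(),
                         sir_plan = default_sir_plan(),
                         tandem_plan = default_tandem_plan(),
                         min_spacing = 150L,
                         id = "synth1", seed = NULL) {
  cfg <- list(length = as.integer(length), gc = gc, genes = genes,
              sir_plan = sir_plan, tandem_plan = tandem_plan,
              min_spacing = as.integer(min_spacing),
              id = id, seed = seed)
  stopifnot(cfg$length >= 1000L, gc > 0, gc < 1)
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic annotated mitogenome with planted repeats
#'
#' Draws an i.i.d. background sequence at the configured GC, lays the gene
#' template around the circle with randomly sized intergenic gaps, plants
#' hairpins and tandem arrays in their intended region class with at least
#' `min_spacing` bp between elements, and emits the truth coordinates of
#' every planted element. Flanking guard bases ensure each planted hairpin
#' is a maximal hit at exactly its planted coordinates when scanned with a
#' mismatch budget equal to the planted mismatch count.
#'
#' @param config A [synth_config()].
#' @return A list with `genome` (a [circular_genome()]), `features` (a
#'   [features()] tibble) and `truth` (list of tibbles `sirs`, `tandems`,
#'   plus `gene_order`, the true symbolic order).
#' @export
generate_genome <- function(config = synth_config()) {
  if (!is.null(config$seed)) {
    return(withr::with_seed(config$seed, generate_genome_impl(config)))
  }
  generate_genome_impl(config)
}

generate_genome_impl <- function(config) {
  n <- config$length
  tmpl <- config$genes
  nfeat <- nrow(tmpl)
  min_gap <- 50L
  extra <- n - sum(tmpl$length) - nfeat * min_gap
  if (extra < 0L) {
    stop("genome length too small for the gene template", call. = FALSE)
  }
  gaps <- min_gap + as.integer(stats::rmultinom(1, extra, rep(1, nfeat)))

  starts <- integer(nfeat)
  pos <- 0L
  for (i in seq_len(nfeat)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + tmpl$length[i]
  }
  feats <- features(
    label = tmpl$label, kind = tmpl$kind,
    start = starts, end = starts + tmpl$length,
    strand = tmpl$strand
  )

  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)

  gap_tbl <- tibble::tibble(
    start = starts - gaps,
    end = starts
  )
  coding_tbl <- tibble::tibble(
    start = starts[tmpl$kind %in% coding_kinds],
    end = (starts + tmpl$length)[tmpl$kind %in% coding_kinds]
  )

  placed <- tibble::tibble(start = integer(), end = integer())
  place_element <- function(len, region, what) {
    slots <- if (region == "coding") coding_tbl else gap_tbl
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    for (k in seq_len(nrow(slots))) {
      lo <- slots$start[k] + 10L
      hi <- slots$end[k] - 10L - len
      if (hi < lo) next
      cand <- seq.int(lo, hi)
      if (nrow(placed) > 0L) {
        ok <- rep(TRUE, length(cand))
        for (r in seq_len(nrow(placed))) {
          ok <- ok & (cand + len + config$min_spacing <= placed$start[r] |
                        cand >= placed$end[r] + config$min_spacing)
        }
        cand <- cand[ok]
      }
      if (length(cand) > 0L) {
        st <- cand[sample.int(length(cand), 1L)]
        placed <<- dplyr::bind_rows(placed, tibble::tibble(start = st, end = st + len))
        return(st)
      }
    }
    stop("cannot place planted element: ", what, call. = FALSE)
  }

  comp1 <- c(A = "T", C = "G", G = "C", T = "A")
  sir_truth <- list()
  if (!is.null(config$sir_plan) && nrow(config$sir_plan) > 0L) {
    for (i in seq_len(nrow(config$sir_plan))) {
      row <- config$sir_plan[i, ]
      for (j in seq_len(row$count)) {
        stem <- sample(seq.int(row$stem_min, row$stem_max), 1L)
        loop <- sample(seq.int(row$loop_min, row$loop_max), 1L)
        len <- 2L * stem + loop
        st <- place_element(len, row$region, paste0(row$hexamer, " hairpin ", j))
        left <- c(sample(c("A", "C", "G", "T"), stem - 6L, replace = TRUE),
                  strsplit(row$hexamer, "")[[1]])
        right <- rev(unname(comp1[left]))
        mm <- as.integer(row$mismatch)
        if (mm > 0L) {
          at <- sample.int(stem, 1L)          # stem pair index from outer end
          ri <- stem - at + 1L                # right-arm base pairing left[at]
          right[ri] <- sample(setdiff(c("A", "C", "G", "T"), comp1[left[at]]), 1L)
        }
        loop_seq <- sample(c("A", "C", "G", "T"), loop, replace = TRUE)
        if (loop >= 2L && loop_seq[loop] == comp1[loop_seq[1]]) {
          loop_seq[loop] <- sample(setdiff(c("A", "C", "G", "T"),
                                           comp1[loop_seq[1]]), 1L)
        }
        b[(st + 1L):(st + len)] <- c(left, loop_seq, right)
        # flank guards: outward extension must always hit a mismatched pair
        guard <- function(p_left, p_right) {
          if (p_left >= 0L && p_right < n) {
            if (b[p_right + 1L] == comp1[b[p_left + 1L]]) {
              b[p_right + 1L] <<- sample(setdiff(c("A", "C", "G", "T"),
                                                 comp1[b[p_left + 1L]]), 1L)
            }
          }
        }
        guard(st - 1L, st + len)
        guard(st - 2L, st + len + 1L)
        sir_truth[[length(sir_truth) + 1L]] <- tibble::tibble(
          genome_id = config$id, family = row$hexamer,
          left_start = st, left_end = st + stem,
          right_start = st + stem + loop, right_end = st + len,
          stem = stem, loop = loop, mismatches = mm,
          region = row$region
        )
      }
    }
  }

  tandem_truth <- list()
  if (!is.null(config$tandem_plan) && nrow(config$tandem_plan) > 0L) {
    for (i in seq_len(nrow(config$tandem_plan))) {
      row <- config$tandem_plan[i, ]
      p <- as.integer(row$period)
      len <- p * as.integer(row$copies)
      st <- place_element(len, "intergenic", paste0("tandem period ", p))
      cons <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
      arr <- rep(cons, length.out = len)
      if (row$identity < 1) {
        nmut <- stats::rbinom(1, len, 1 - row$identity)
        if (nmut > 0L) {
          at <- sample.int(len, nmut)
          arr[at] <- vapply(arr[at], function(x) {
            sample(setdiff(c("A", "C", "G", "T"), x), 1L)
          }, character(1))
        }
      }
      b[(st + 1L):(st + len)] <- arr
      # period-consistency guards: stop array extension at the boundary
      if (st - 1L >= 0L && b[st] == b[st + p]) {
        b[st] <- sample(setdiff(c("A", "C", "G", "T"), b[st + p]), 1L)
      }
      if (st + len < n && b[st + len + 1L] == b[st + len + 1L - p]) {
        b[st + len + 1L] <- sample(setdiff(c("A", "C", "G", "T"),
                                           b[st + len + 1L - p]), 1L)
      }
      tandem_truth[[length(tandem_truth) + 1L]] <- tibble::tibble(
        genome_id = config$id, start = st, end = st + len,
        period = p, copies = as.numeric(row$copies),
        consensus = paste(cons, collapse = "")
      )
    }
  }

  genome <- circular_genome(paste(b, collapse = ""), id = config$id,
                            topology = "circular")
  truth <- list(
    sirs = if (length(sir_truth) > 0L) dplyr::bind_rows(sir_truth) else NULL,
    tandems = if (length(tandem_truth) > 0L) dplyr::bind_rows(tandem_truth) else NULL,
    gene_order = extract_gene_order(feats, genome_id = config$id),
    full_order = tibble::tibble(label = tmpl$label, kind = tmpl$kind,
                                strand = tmpl$strand)
  )
  list(genome = genome, features = feats, truth = truth)
}

# ---- tree-guided rearrangement simulation ---------------------------------

# Coordinate mapper for a segment operation on [lo, hi) with insertion
# point ins (post-removal coordinate, translocation only).
make_mapper <- function(type, lo, hi, ins = NULL) {
  seg <- hi - lo
  if (type == "inversion") {
    function(start, end) {
      inside <- start >= lo & end <= hi
      outside <- end <= lo | start >= hi
      if (any(!inside & !outside)) stop("interval straddles the event span", call. = FALSE)
      ns <- ifelse(inside, lo + (hi - end), start)
      ne <- ifelse(inside, lo + (hi - start), end)
      list(start = as.integer(ns), end = as.integer(ne), flipped = inside)
    }
  } else {
    function(start, end) {
      inside <- start >= lo & end <= hi
      outside <- end <= lo | start >= hi
      if (any(!inside & !outside)) stop("interval straddles the event span", call. = FALSE)
      # removal
      ns <- ifelse(inside, start - lo, ifelse(start >= hi, start - seg, start))
      ne <- ifelse(inside, end - lo, ifelse(end > hi, end - seg, end))
      # insertion at ins
      ns <- ifelse(inside, ns + ins, ifelse(ns >= ins, ns + seg, ns))
      ne <- ifelse(inside, ne + ins, ifelse(ne > ins, ne + seg, ne))
      list(start = as.integer(ns), end = as.integer(ne), flipped = rep(FALSE, length(ns)))
    }
  }
}

apply_event <- function(state, type, from_unit, to_unit, after_unit = NA) {
  f <- state$features
  span_of <- function(lab) {
    rows <- f[f$label == lab, , drop = FALSE]
    if (nrow(rows) == 0L) stop("unknown unit in event plan: ", lab, call. = FALSE)
    c(min(rows$start), max(rows$end))
  }
  lo <- span_of(from_unit)[1]
  hi <- span_of(to_unit)[2]
  if (hi <= lo) stop("event span is empty or wraps the origin: ",
                     from_unit, "..", to_unit, call. = FALSE)
  n <- genome_length(state$genome)
  s <- strsplit(state$genome$sequence, "")[[1]]

  if (type == "inversion") {
    s[(lo + 1L):hi] <- rev(chartr("ACGTN", "TGCAN", s[(lo + 1L):hi]))
    mapper <- make_mapper("inversion", lo, hi)
  } else if (type == "translocation") {
    ins0 <- span_of(after_unit)[2]
    if (ins0 > lo && ins0 <= hi) stop("translocation target inside the span", call. = FALSE)
    seg <- s[(lo + 1L):hi]
    rest <- s[-((lo + 1L):hi)]
    ins <- if (ins0 <= lo) ins0 else ins0 - (hi - lo)
    s <- append(rest, seg, after = ins)
    mapper <- make_mapper("translocation", lo, hi, ins)
  } else {
    stop("unknown event type: ", type, call. = FALSE)
  }

  mp <- mapper(f$start, f$end)
  f$start <- mp$start
  f$end <- mp$end
  f$strand <- ifelse(mp$flipped, ifelse(f$strand == "+", "-", "+"), f$strand)

  # symbolic order bookkeeping (independent of coordinates)
  fo <- state$full_order
  i1 <- match(from_unit, fo$label)
  i2 <- match(to_unit, fo$label)
  if (is.na(i1) || is.na(i2) || i2 < i1) {
    stop("event span not contiguous in the symbolic order", call. = FALSE)
  }
  idx <- seq.int(i1, i2)
  if (type == "inversion") {
    block <- fo[idx, , drop = FALSE]
    block <- block[rev(seq_len(nrow(block))), , drop = FALSE]
    block$strand <- ifelse(block$strand == "+", "-", "+")
    fo[idx, ] <- block
  } else {
    seg_rows <- fo[idx, , drop = FALSE]
    rest_rows <- fo[-idx, , drop = FALSE]
    at <- match(after_unit, rest_rows$label)
    fo <- dplyr::bind_rows(
      rest_rows[seq_len(at), , drop = FALSE],
      seg_rows,
      if (at < nrow(rest_rows)) rest_rows[seq.int(at + 1L, nrow(rest_rows)), , drop = FALSE]
    )
  }

  truth <- state$truth
  for (nm in c("sirs", "tandems")) {
    tb <- truth[[nm]]
    if (is.null(tb)) next
    if (nm == "sirs") {
      mp2 <- mapper(tb$left_start, tb$right_end)
      w <- tb$right_end - tb$left_start
      tb$left_start <- mp2$start
      tb$right_end <- mp2$end
      tb$left_end <- tb$left_start + tb$stem
      tb$right_start <- tb$right_end - tb$stem
      tb$family <- ifelse(mp2$flipped, dna_revcomp(tb$family), tb$family)
    } else {
      mp2 <- mapper(tb$start, tb$end)
      tb$start <- mp2$start
      tb$end <- mp2$end
    }
    truth[[nm]] <- tb
  }

  list(
    genome = circular_genome(paste(s, collapse = ""), id = state$genome$id,
                             topology = "circular"),
    features = f,
    truth = truth,
    full_order = fo
  )
}

#' Evolve a synthetic genome along a tree with planned rearrangements
#'
#' Applies inversion/translocation events to whole gene-unit spans along
#' each root-to-tip path of the tree. Sequence segments move and flip with
#' their annotations and with the planted-repeat truth coordinates; a
#' symbolic gene order is maintained independently of coordinates as
#' per-tip truth. Events are content-preserving: every tip has the same
#' genome length and gene complement as the root.
#'
#' @param root A [generate_genome()] result.
#' @param tree An `ape::phylo`, Newick string, or Newick file; tip labels
#'   name the output genomes.
#' @param plan A tibble with columns `node` (tip label or internal node
#'   name), `type` (`"inversion"` or `"translocation"`), `from_unit`,
#'   `to_unit` (feature labels bounding the contiguous span) and
#'   `after_unit` (translocation destination; segment inserted after this
#'   unit). Events on one edge apply in plan order.
#' @return A list of class `synth_cohort`: `tips` (named list with
#'   `genome`, `features`, `truth`, `full_order` per tip), `plan`, `tree`.
#' @export
evolve_along_tree <- function(root, tree, plan = NULL) {
  tree <- as_phylo(tree)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  if (is.null(plan)) {
    plan <- tibble::tibble(node = character(), type = character(),
                           from_unit = character(), to_unit = character(),
                           after_unit = character())
  }
  node_key <- function(node) {
    if (node <= ntip) tree$tip.label[node] else node_label_of(tree, node)
  }
  root_state <- list(genome = root$genome, features = root$features,
                     truth = root$truth, full_order = root$truth$full_order)
  states <- list()
  states[[as.character(ntip + 1L)]] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    st <- states[[as.character(parent)]]
    key <- node_key(child)
    ev <- plan[plan$node == key, , drop = FALSE]
    if (nrow(ev) > 0L) {
      for (r in seq_len(nrow(ev))) {
        st <- apply_event(st, ev$type[r], ev$from_unit[r], ev$to_unit[r],
                          if ("after_unit" %in% names(ev)) ev$after_unit[r] else NA)
      }
    }
    states[[as.character(child)]] <- st
  }
  tips <- lapply(seq_len(ntip), function(i) {
    st <- states[[as.character(i)]]
    st$genome$id <- tree$tip.label[i]
    st$truth$gene_order <- symbolic_gene_order(st$full_order, tree$tip.label[i])
    st
  })
  names(tips) <- tree$tip.label
  structure(list(tips = tips, plan = plan, tree = tree),
            class = "synth_cohort")
}

symbolic_gene_order <- function(full_order, genome_id) {
  keep <- !full_order$kind %in% c("orf_unknown", "intron_groupI", "intron_groupII")
  tb <- full_order[keep, , drop = FALSE]
  new_gene_order(
    tibble::tibble(position = seq_len(nrow(tb)), label = tb$label,
                   strand = tb$strand),
    genome_id
  )
}
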
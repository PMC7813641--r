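# Signed circular gene-order comparison: conserved-section merging,
# section orders, breakpoint distances, and event mapping on a tree.

order_units <- function(order) {
  if (all(c("label", "strand") %in% names(order))) {
    tibble::tibble(label = order$label, sign = ifelse(order$strand == "+", 1L, -1L))
  } else if (all(c("section", "orientation") %in% names(order))) {
    tibble::tibble(label = order$section, sign = ifelse(order$orientation == "+", 1L, -1L))
  } else {
    stop("not a gene order or section order", call. = FALSE)
  }
}

# Canonical key of the signed adjacency u(su) -> v(sv); the signed reversal
# v(-sv) -> u(-su) maps to the same key.
canon_adj <- function(u, su, v, sv) {
  if (u < v) paste(u, su, v, sv) else paste(v, -sv, u, -su)
}

# All signed circular adjacencies of an order, as canonical keys.
adjacency_set <- function(order) {
  un <- order_units(order)
  k <- nrow(un)
  if (k < 2L) return(character(0))
  nxt <- c(seq_len(k)[-1], 1L)
  vapply(seq_len(k), function(i) {
    canon_adj(un$label[i], un$sign[i], un$label[nxt[i]], un$sign[nxt[i]])
  }, character(1))
}

#' Merge gene units into conserved sections across genomes
#'
#' Two units are linked when, in every genome containing both, they are
#' adjacent with identical relative orientation (a signed reversal --
#' `-b, -a` versus `+a, +b` -- counts as the same adjacency). Connected
#' components of the link relation are the conserved sections; a unit
#' present in only one genome forms a singleton section. A fully conserved
#' circle collapses to a single section with a declared break at the first
#' unit of the first genome. Sections are labelled `A`, `B`, ... by the
#' position of their first member in the first input genome.
#'
#' @param orders A named list (>= 2) of [extract_gene_order()] tibbles.
#' @return An object of class `section_set`: list with `sections` (tibble
#'   `section`, `seq`, `label`, `strand` giving each section's reference
#'   member order) and `genomes` (the input genome ids).
#' @export
merge_sections <- function(orders) {
  stopifnot(is.list(orders), length(orders) >= 2L)
  ids <- names(orders)
  if (is.null(ids) || any(ids == "")) {
    ids <- vapply(seq_along(orders), function(i) {
      attr(orders[[i]], "genome_id") %||% paste0("g", i)
    }, character(1))
  }
  units_by_genome <- lapply(orders, order_units)
  names(units_by_genome) <- ids

  # genomes containing each unit
  presence <- list()
  for (g in ids) {
    for (lab in units_by_genome[[g]]$label) {
      presence[[lab]] <- c(presence[[lab]], g)
    }
  }

  # per-genome adjacency lookup: pair key -> signed canonical key
  adj_by_genome <- lapply(ids, function(g) {
    un <- units_by_genome[[g]]
    k <- nrow(un)
    if (k < 2L) return(list())
    nxt <- c(seq_len(k)[-1], 1L)
    keys <- vapply(seq_len(k), function(i) {
      paste(sort(c(un$label[i], un$label[nxt[i]])), collapse = "\r")
    }, character(1))
    vals <- vapply(seq_len(k), function(i) {
      canon_adj(un$label[i], un$sign[i], un$label[nxt[i]], un$sign[nxt[i]])
    }, character(1))
    as.list(stats::setNames(vals, keys))
  })
  names(adj_by_genome) <- ids

  # candidate pairs: adjacent somewhere; linked iff adjacent with the same
  # signed relation in every genome containing both. A unit private to a
  # single genome is a singleton section and never links.
  private_units <- names(presence)[vapply(presence, length, integer(1)) == 1L]
  cand <- unique(unlist(lapply(adj_by_genome, names)))
  links <- list()
  for (pk in cand) {
    uv <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    if (any(uv %in% private_units)) next
    both <- intersect(presence[[uv[1]]], presence[[uv[2]]])
    sigs <- vapply(both, function(g) {
      s <- adj_by_genome[[g]][[pk]]
      if (is.null(s)) NA_character_ else s
    }, character(1))
    if (!anyNA(sigs) && length(unique(sigs)) == 1L) {
      links[[pk]] <- sigs[[1]]
    }
  }

  # units with more than two link partners cannot sit inside a linear
  # section; leave them unmerged
  all_units <- unique(unlist(lapply(units_by_genome, function(u) u$label)))
  if (length(links) > 0L) {
    ends <- unlist(strsplit(names(links), "\r", fixed = TRUE))
    deg <- table(ends)
    bad <- names(deg)[deg > 2L]
    if (length(bad) > 0L) {
      rlang::inform(paste0("inconsistent adjacency data; left unmerged: ",
                           paste(bad, collapse = ", ")))
      drop <- vapply(names(links), function(pk) {
        any(strsplit(pk, "\r", fixed = TRUE)[[1]] %in% bad)
      }, logical(1))
      links <- links[!drop]
    }
  }

  comps <- link_components(all_units, names(links))
  first_units <- units_by_genome[[ids[1]]]$label

  section_rows <- list()
  sort_keys <- list()
  for (comp in comps) {
    path <- assemble_section_path(comp, links)
    path <- orient_section(path, units_by_genome, ids)
    # deterministic placement: first genome containing a member, then the
    # position of the earliest member there
    home <- which(vapply(ids, function(g) {
      any(path$label %in% units_by_genome[[g]]$label)
    }, logical(1)))[1]
    pos <- min(match(path$label, units_by_genome[[ids[home]]]$label), na.rm = TRUE)
    section_rows[[length(section_rows) + 1L]] <- path
    sort_keys[[length(sort_keys) + 1L]] <- c(home, pos)
  }
  ord <- order(vapply(sort_keys, `[`, numeric(1), 1),
               vapply(sort_keys, `[`, numeric(1), 2))
  sections <- purrr::map_dfr(seq_along(ord), function(i) {
    path <- section_rows[[ord[i]]]
    tibble::tibble(
      section = section_label(i),
      seq = seq_len(nrow(path)),
      label = path$label,
      strand = ifelse(path$sign > 0L, "+", "-")
    )
  })
  structure(list(sections = sections, genomes = ids), class = "section_set")
}

section_label <- function(i) {
  if (i <= 26L) LETTERS[i] else paste0(LETTERS[(i - 1L) %/% 26L], LETTERS[(i - 1L) %% 26L + 1L])
}

link_components <- function(units, pair_keys) {
  parent <- stats::setNames(seq_along(units), units)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (pk in pair_keys) {
    uv <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    ri <- find(match(uv[1], units))
    rj <- find(match(uv[2], units))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(units), find, numeric(1))
  split(units, roots)
}

# Chain a component's links into an ordered signed path. Cycles (fully
# conserved circles) are broken before the component's lexicographically
# first unit.
assemble_section_path <- function(members, links) {
  if (length(members) == 1L) {
    return(tibble::tibble(label = members, sign = 1L))
  }
  rel <- list()  # per unit: list of (other, p, q): unit@p -> other@q
  for (pk in names(links)) {
    uv <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    if (!all(uv %in% members)) next
    parts <- strsplit(links[[pk]], " ", fixed = TRUE)[[1]]
    x <- parts[1]; sx <- as.integer(parts[2])
    y <- parts[3]; sy <- as.integer(parts[4])
    rel[[x]] <- c(rel[[x]], list(list(other = y, p = sx, q = sy)))
    rel[[y]] <- c(rel[[y]], list(list(other = x, p = -sy, q = -sx)))
  }
  deg <- vapply(members, function(u) length(rel[[u]]), integer(1))
  start <- if (any(deg == 1L)) {
    sort(members[deg == 1L])[1]
  } else {
    sort(members)[1]  # cycle: break before this unit
  }
  # walk forward: start's sign is its predecessor role in its first relation
  first_rel <- rel[[start]][[1]]
  labs <- start
  signs <- first_rel$p
  prev <- start
  cur <- first_rel$other
  cur_sign <- first_rel$q
  while (!cur %in% labs) {
    labs <- c(labs, cur)
    signs <- c(signs, cur_sign)
    nxts <- rel[[cur]]
    nxt <- NULL
    for (r in nxts) {
      if (r$other != prev && r$p == cur_sign) {
        nxt <- r
        break
      }
    }
    if (is.null(nxt)) break
    prev <- cur
    cur <- nxt$other
    cur_sign <- nxt$q
  }
  if (length(labs) != length(members)) {
    # orientation chain conflict: fall back to an unordered listing
    rlang::inform(paste0("could not chain section members consistently: ",
                         paste(members, collapse = ", ")))
    return(tibble::tibble(label = sort(members), sign = 1L))
  }
  tibble::tibble(label = labs, sign = as.integer(signs))
}

# Flip the whole section, if needed, so its reference order matches its
# appearance in the earliest input genome that shows any of its adjacencies.
orient_section <- function(path, units_by_genome, ids) {
  if (nrow(path) == 1L) {
    for (g in ids) {
      un <- units_by_genome[[g]]
      i <- match(path$label, un$label)
      if (!is.na(i)) {
        path$sign <- un$sign[i]
        return(path)
      }
    }
    return(path)
  }
  for (g in ids) {
    un <- units_by_genome[[g]]
    present <- path$label[path$label %in% un$label]
    if (length(present) == 0L) next
    i <- match(present[1], un$label)
    j <- match(present[1], path$label)
    if (un$sign[i] == path$sign[j]) return(path)
    path$label <- rev(path$label)
    path$sign <- -rev(path$sign)
    return(path)
  }
  path
}

#' @export
print.section_set <- function(x, ...) {
  secs <- split(x$sections, x$sections$section)
  cat(sprintf("<section_set> %d sections over %d genomes\n",
              length(secs), length(x$genomes)))
  for (nm in unique(x$sections$section)) {
    s <- x$sections[x$sections$section == nm, , drop = FALSE]
    cat(sprintf("  %s: %s\n", nm,
                paste0(s$strand, s$label, collapse = " ")))
  }
  invisible(x)
}

#' @rdname merge_sections
#' @param x A `section_set`.
#' @param ... Unused.
#' @method tidy section_set
#' @export
tidy.section_set <- function(x, ...) x$sections

#' @rdname merge_sections
#' @method glance section_set
#' @export
glance.section_set <- function(x, ...) {
  sizes <- table(x$sections$section)
  tibble::tibble(
    n_sections = length(sizes),
    n_singleton = sum(sizes == 1L),
    n_multigene = sum(sizes > 1L),
    n_units = nrow(x$sections),
    n_genomes = length(x$genomes)
  )
}

#' Rewrite a genome as a signed circular sequence of sections
#'
#' Each maximal run of units belonging to one section becomes one signed
#' token: positive when the members appear in the section's reference order
#' and orientation, negative for the exact signed reversal. A section whose
#' members are non-contiguous in this genome violates the merge invariant
#' and raises an error.
#'
#' @param order A [extract_gene_order()] tibble for one genome.
#' @param sections A [merge_sections()] result from a cohort containing it.
#' @return A tibble of class `section_order` with columns `position`,
#'   `section`, `orientation`.
#' @export
section_order <- function(order, sections) {
  un <- order_units(order)
  k <- nrow(un)
  if (k == 0L) {
    return(structure(tibble::tibble(position = integer(), section = character(),
                                    orientation = character()),
                     class = c("section_order", class(tibble::tibble()))))
  }
  sec_of <- stats::setNames(sections$sections$section, sections$sections$label)
  if (any(!un$label %in% names(sec_of))) {
    stop("units missing from the section set: ",
         paste(setdiff(un$label, names(sec_of)), collapse = ", "), call. = FALSE)
  }
  sec_seq <- unname(sec_of[un$label])

  # rotate the circle to start at a section boundary
  if (k > 1L && length(unique(sec_seq)) > 1L) {
    brk <- which(sec_seq != dplyr::lag(sec_seq, default = sec_seq[k]))[1]
    rot <- c(seq.int(brk, k), seq_len(brk - 1L))
    un <- un[rot, , drop = FALSE]
    sec_seq <- sec_seq[rot]
  }
  runs <- rle(sec_seq)
  if (anyDuplicated(runs$values)) {
    stop("section members are non-contiguous in this genome: ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "),
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  orientation <- character(length(runs$values))
  for (r in seq_along(runs$values)) {
    run <- un[seq.int(starts[r], ends[r]), , drop = FALSE]
    ref <- sections$sections[sections$sections$section == runs$values[r], , drop = FALSE]
    ref <- ref[ref$label %in% run$label, , drop = FALSE]
    ref_sign <- ifelse(ref$strand == "+", 1L, -1L)
    if (length(runs$values) == 1L && nrow(run) > 1L) {
      # the whole circle is one section: align the arbitrary rotation
      rot_to <- function(tb, lab) {
        i0 <- match(lab, tb$label)
        if (is.na(i0) || i0 == 1L) return(tb)
        tb[c(seq.int(i0, nrow(tb)), seq_len(i0 - 1L)), , drop = FALSE]
      }
      fwd_run <- rot_to(run, ref$label[1])
      flip <- tibble::tibble(label = rev(run$label), sign = -rev(run$sign))
      rev_run <- rot_to(flip, ref$label[1])
      if (identical(fwd_run$label, ref$label) &&
          identical(fwd_run$sign, ref_sign)) {
        orientation[r] <- "+"
      } else if (identical(rev_run$label, ref$label) &&
                 identical(rev_run$sign, ref_sign)) {
        orientation[r] <- "-"
      } else {
        stop("units of section ", runs$values[r],
             " do not match its reference order in this genome", call. = FALSE)
      }
      next
    }
    fwd <- identical(run$label, ref$label) && identical(run$sign, ref_sign)
    rev_ok <- identical(run$label, rev(ref$label)) &&
      identical(run$sign, -rev(ref_sign))
    if (fwd) {
      orientation[r] <- "+"
    } else if (rev_ok) {
      orientation[r] <- "-"
    } else {
      stop("units of section ", runs$values[r],
           " do not match its reference order in this genome", call. = FALSE)
    }
  }
  out <- tibble::tibble(position = seq_along(runs$values),
                        section = runs$values,
                        orientation = orientation)
  attr(out, "genome_id") <- attr(order, "genome_id")
  class(out) <- unique(c("section_order", class(out)))
  out
}

#' Breakpoint distance between two signed circular orders
#'
#' The number of signed circular adjacencies present in `order_a` but absent
#' in `order_b`, after restricting both to their shared units. Zero iff the
#' orders are equivalent up to rotation and full signed reflection.
#'
#' @param order_a,order_b Gene orders or section orders.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(order_a, order_b) {
  ua <- order_units(order_a)
  ub <- order_units(order_b)
  shared <- intersect(ua$label, ub$label)
  if (length(shared) < 2L) {
    stop("breakpoint distance undefined: fewer than 2 shared units", call. = FALSE)
  }
  ra <- ua[ua$label %in% shared, , drop = FALSE]
  rb <- ub[ub$label %in% shared, , drop = FALSE]
  adj <- function(un) {
    k <- nrow(un)
    nxt <- c(seq_len(k)[-1], 1L)
    vapply(seq_len(k), function(i) {
      canon_adj(un$label[i], un$sign[i], un$label[nxt[i]], un$sign[nxt[i]])
    }, character(1))
  }
  sum(!(adj(ra) %in% adj(rb)))
}

#' Map gene-order changes onto the edges of a tree
#'
#' For every edge, compares the adjacency content of the descendant tips
#' against the remaining tips: an adjacency present in every descendant tip
#' but in no other tip is reported as gained below the edge, and vice versa
#' as lost. This is a descriptive Fitch-style change list, not an ancestral
#' genome reconstruction. Changes at unresolved polytomies are reported on
#' the polytomy's edges and flagged.
#'
#' @param orders Named list of per-genome orders (gene orders or section
#'   orders); names must match the tree's tip labels.
#' @param tree An `ape::phylo` object, a Newick string, or a Newick file
#'   path.
#' @return A tibble with one row per edge: `parent`, `node`, `node_label`,
#'   `n_tips`, `at_polytomy`, `n_gained`, `n_lost` and list-columns
#'   `gained`/`lost` of adjacency keys.
#' @export
map_events_on_tree <- function(orders, tree) {
  tree <- as_phylo(tree)
  tips <- tree$tip.label
  if (!all(tips %in% names(orders))) {
    stop("orders missing for tips: ",
         paste(setdiff(tips, names(orders)), collapse = ", "), call. = FALSE)
  }
  adj <- lapply(orders[tips], adjacency_set)
  ntip <- length(tips)
  desc_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  child_count <- table(tree$edge[, 1])
  out <- purrr::map_dfr(seq_len(nrow(tree$edge)), function(e) {
    parent <- tree$edge[e, 1]
    node <- tree$edge[e, 2]
    below <- desc_tips(node)
    above <- setdiff(tips, below)
    if (length(above) == 0L) return(NULL)
    in_all_below <- Reduce(intersect, adj[below])
    in_any_above <- unique(unlist(adj[above]))
    in_all_above <- Reduce(intersect, adj[above])
    in_any_below <- unique(unlist(adj[below]))
    gained <- setdiff(in_all_below, in_any_above)
    lost <- setdiff(in_all_above, in_any_below)
    tibble::tibble(
      parent = parent,
      node = node,
      node_label = if (node <= ntip) tips[node] else node_label_of(tree, node),
      n_tips = length(below),
      at_polytomy = unname(child_count[as.character(parent)] > 2L),
      n_gained = length(gained),
      n_lost = length(lost),
      gained = list(gained),
      lost = list(lost)
    )
  })
  out
}

node_label_of <- function(tree, node) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (!is.null(lab) && length(lab) >= node - ntip && nzchar(lab[node - ntip])) {
    lab[node - ntip]
  } else {
    paste0("node", node)
  }
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("cannot interpret tree input", call. = FALSE)
}
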
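# Independent oracles used across the suite. These re-derive expected
# results by direct enumeration or naive recomputation, sharing no code
# with the implementation paths they check.

# Brute-force maximal inverted-repeat enumeration on a linear sequence:
# for every loop placement (start a, length g) and every stem length L,
# count mismatched pairs directly and keep exactly the hits that cannot be
# extended outward or into the loop.
oracle_palindromes <- function(seq_chr, min_stem = 6L, max_stem = 100L,
                               max_loop = 10L, max_mismatch = 1L) {
  s <- strsplit(toupper(seq_chr), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")[s]
  n <- length(s)
  rows <- list()
  for (g in 0:max_loop) {
    a_max <- n - g
    if (a_max < 2L) next
    for (a in 2:a_max) {
      tmax_seq <- min(a - 1L, n - a - g + 1L)
      if (tmax_seq < 1L) next
      tmax <- min(tmax_seq, max_stem + 1L)
      t <- seq_len(tmax)
      miss <- s[a - t] != comp[a + g - 1L + t]
      cmm <- cumsum(miss)
      miss_in <- if (g >= 2L) s[a] != comp[a + g - 1L] else NA
      L_max <- min(tmax_seq, max_stem)
      if (L_max < min_stem) next
      Ls <- seq.int(min_stem, L_max)
      mm <- cmm[Ls]
      valid <- mm <= max_mismatch
      out_ok <- (Ls < max_stem) & (Ls + 1L <= tmax_seq) &
        (cmm[pmin(Ls + 1L, tmax)] <= max_mismatch)
      in_ok <- if (g >= 2L) {
        (Ls < max_stem) & (mm + miss_in <= max_mismatch)
      } else {
        rep(FALSE, length(Ls))
      }
      keep <- valid & !out_ok & !in_ok
      if (any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = a - 1L - Ls[keep],
          stem_len = Ls[keep],
          loop_len = g,
          mismatches = mm[keep]
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(left_start = integer(), stem_len = integer(),
                      loop_len = integer(), mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$left_start, -out$stem_len, out$loop_len), , drop = FALSE]
}

hit_key <- function(df) {
  sort(paste(df$left_start, df$stem_len, df$loop_len, df$mismatches))
}

# Plain-R wraparound alignment (row-by-row DP with a two-pass cyclic
# sweep), independent of the compiled scorer.
oracle_wrap_score <- function(region_chr, consensus_chr,
                              match = 2, mismatch = 7, indel = 7) {
  r <- strsplit(region_chr, "")[[1]]
  cons <- strsplit(consensus_chr, "")[[1]]
  m <- length(r)
  d <- length(cons)
  prev <- rep(0, d)
  for (i in seq_len(m)) {
    cur <- rep(-Inf, d)
    for (sweep in 1:2) {
      for (j in seq_len(d)) {
        jm1 <- if (j == 1L) d else j - 1L
        sub <- if (r[i] == cons[j] && r[i] != "N") match else -mismatch
        best <- max(prev[jm1] + sub, prev[j] - indel, cur[jm1] - indel)
        if (best > cur[j]) cur[j] <- best
      }
    }
    prev <- cur
  }
  max(prev)
}

# Adjacency-set difference by direct scanning (no canonical-key machinery):
# an adjacency of A is "in B" if B shows the same ordered signed pair
# forward, or the flipped pair in the reverse reading.
oracle_breakpoints <- function(labels_a, signs_a, labels_b, signs_b) {
  shared <- intersect(labels_a, labels_b)
  ka <- which(labels_a %in% shared)
  kb <- which(labels_b %in% shared)
  la <- labels_a[ka]; sa <- signs_a[ka]
  lb <- labels_b[kb]; sb <- signs_b[kb]
  k <- length(la)
  nxt <- function(i, len) if (i == len) 1L else i + 1L
  in_b <- function(u, su, v, sv) {
    len <- length(lb)
    for (i in seq_len(len)) {
      j <- nxt(i, len)
      if (lb[i] == u && sb[i] == su && lb[j] == v && sb[j] == sv) return(TRUE)
      if (lb[i] == v && sb[i] == -sv && lb[j] == u && sb[j] == -su) return(TRUE)
    }
    FALSE
  }
  d <- 0L
  for (i in seq_len(k)) {
    j <- nxt(i, k)
    if (!in_b(la[i], sa[i], la[j], sa[j])) d <- d + 1L
  }
  d
}

# Truth sections by direct pairwise-adjacency conservation on symbolic
# orders: two units are co-sectioned iff adjacent with identical relative
# orientation in every genome containing both; components found by
# repeated expansion.
oracle_sections <- function(orders) {
  unit_tbls <- lapply(orders, function(o) {
    data.frame(label = o$label, sign = ifelse(o$strand == "+", 1L, -1L))
  })
  all_units <- unique(unlist(lapply(unit_tbls, function(u) u$label)))
  n_genomes_with <- function(u) {
    sum(vapply(unit_tbls, function(tb) u %in% tb$label, logical(1)))
  }
  adjacent_same <- function(u, v) {
    # a unit private to one genome is always a singleton
    if (n_genomes_with(u) < 2L || n_genomes_with(v) < 2L) return(FALSE)
    seen <- FALSE
    for (tb in unit_tbls) {
      iu <- match(u, tb$label)
      iv <- match(v, tb$label)
      if (is.na(iu) || is.na(iv)) next
      k <- nrow(tb)
      j <- if (iu == k) 1L else iu + 1L
      jp <- if (iu == 1L) k else iu - 1L
      sig <- NULL
      if (j == iv) {
        sig <- c(tb$sign[iu], tb$sign[iv])
      } else if (jp == iv) {
        # v precedes u: read the pair in reverse as u -> v
        sig <- c(-tb$sign[iu], -tb$sign[iv])
      }
      if (is.null(sig)) return(FALSE)
      if (!seen) {
        ref <- sig
        seen <- TRUE
      } else if (!identical(sig, ref)) {
        return(FALSE)
      }
    }
    seen
  }
  groups <- list()
  assigned <- character(0)
  for (u in all_units) {
    if (u %in% assigned) next
    grp <- u
    repeat {
      grew <- FALSE
      for (v in setdiff(all_units, c(assigned, grp))) {
        if (any(vapply(grp, function(w) adjacent_same(w, v) || adjacent_same(v, w),
                       logical(1)))) {
          grp <- c(grp, v)
          grew <- TRUE
        }
      }
      if (!grew) break
    }
    groups[[length(groups) + 1L]] <- sort(grp)
    assigned <- c(assigned, grp)
  }
  groups[order(vapply(groups, `[`, character(1), 1))]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A planted array counts as recovered when one report covers >= 90% of the
# truth span with little overhang and a compatible period (equal, or an
# integer divisor/multiple). Imperfect arrays may shed mutated edge bases.
tandem_recovered <- function(td, truth_row) {
  cand <- td[td$end > truth_row$start & td$start < truth_row$end, , drop = FALSE]
  if (nrow(cand) != 1L) return(FALSE)
  span <- truth_row$end - truth_row$start
  covered <- min(cand$end, truth_row$end) - max(cand$start, truth_row$start)
  if (covered < 0.9 * span) return(FALSE)
  if (cand$start < truth_row$start - 15 || cand$end > truth_row$end + 15) {
    return(FALSE)
  }
  ratio <- cand$period / truth_row$period
  ratio == 1 || ratio == round(ratio) || (1 / ratio) == round(1 / ratio)
}
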
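test_that("planted hairpins are found with the documented geometry", {
  # perfect GC-rich hairpin, flanks cannot pair
  h0 <- find_palindromes("AGGCGCCTTTGGCGCCA", palindrome_params(max_mismatch = 0))
  expect_equal(nrow(h0), 1L)
  expect_equal(h0$left_start, 1L)
  expect_equal(h0$left_end, 7L)
  expect_equal(h0$right_start, 10L)
  expect_equal(h0$right_end, 16L)
  expect_equal(h0$stem_len, 6L)
  expect_equal(h0$loop_len, 3L)
  expect_equal(h0$mismatches, 0L)
  expect_equal(h0$hexamer, "GGCGCC")

  # one substituted pair consumes the mismatch budget
  h1 <- find_palindromes("AGGCGCCTTTGGCACCA", palindrome_params(max_mismatch = 1))
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$stem_len, 6L)
  expect_equal(h1$loop_len, 3L)
  expect_equal(h1$mismatches, 1L)

  # A/T pairing
  h2 <- find_palindromes("AAAAAAGGTTTTTT", palindrome_params(max_mismatch = 0))
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$stem_len, 6L)
  expect_equal(h2$loop_len, 2L)
  expect_equal(h2$hexamer, "AAAAAA")
})

test_that("stem > loop selection is strict", {
  hits <- tibble::tibble(stem_len = c(6L, 6L, 7L), loop_len = c(3L, 8L, 7L))
  kept <- filter_stem_gt_loop(hits)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$stem_len, 6L)
  expect_equal(kept$loop_len, 3L)
})

test_that("hexamer classification reads the loop-adjacent six bases of the left arm", {
  # stem 8: left arm TAGGCGCC, class is the loop-adjacent six
  s <- paste0("T", "TAGGCGCC", "AAA", "GGCGCCTA", "T")
  h <- find_palindromes(s, palindrome_params(max_mismatch = 0))
  big <- h[h$stem_len == 8L, ]
  expect_equal(nrow(big), 1L)
  expect_equal(big$hexamer, "GGCGCC")

  # AT-family hairpin classifies from the left arm, not the right
  sg <- generate_genome(synth_config(
    length = 6000, sir_plan = tibble::tibble(
      hexamer = "AAAAAA", count = 3L, stem_min = 6L, stem_max = 8L,
      loop_min = 0L, loop_max = 2L, mismatch = 1L, region = "intergenic"
    ),
    tandem_plan = NULL, genes = placozoan_gene_template()[1:6, ],
    seed = 21
  ))
  hits <- find_palindromes(sg$genome)
  tr <- sg$truth$sirs
  m <- match(paste(tr$left_start, tr$right_end),
             paste(hits$left_start, hits$right_end))
  expect_false(anyNA(m))
  expect_true(all(hits$hexamer[m] == "AAAAAA"))
})

test_that("repeat types are called at the >= 10 per-genome threshold", {
  hits <- tibble::tibble(hexamer = c(rep("GGATCC", 10), rep("CCGTAC", 9)))
  roster <- call_repeat_types(hits)
  expect_equal(roster$hexamer, "GGATCC")
  expect_equal(roster$n, 10L)
  expect_equal(nrow(call_repeat_types(tibble::tibble(hexamer = character()))), 0L)
})

test_that("scan equals the brute-force enumeration oracle on random sequences", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(150:450, 1)
    s <- random_dna(n, gc = runif(1, 0.3, 0.6))
    imp <- find_palindromes(s, palindrome_params())
    ora <- oracle_palindromes(s)
    expect_identical(hit_key(imp), hit_key(ora))
  }
  # zero-mismatch variant and a longer sequence
  s <- random_dna(1200)
  expect_identical(
    hit_key(find_palindromes(s, palindrome_params(max_mismatch = 0))),
    hit_key(oracle_palindromes(s, max_mismatch = 0))
  )
})

test_that("every emitted hit satisfies the parameter constraints", {
  set.seed(55)
  pp <- palindrome_params(min_stem = 5, max_stem = 12, max_loop = 6,
                          max_mismatch = 1)
  for (i in 1:5) {
    s <- random_dna(800)
    h <- find_palindromes(s, pp)
    expect_true(all(h$stem_len >= 5 & h$stem_len <= 12))
    expect_true(all(h$loop_len >= 0 & h$loop_len <= 6))
    expect_true(all(h$mismatches <= 1))
    expect_equal(h$left_end - h$left_start, h$stem_len)
    expect_equal(h$right_end - h$right_start, h$stem_len)
    expect_equal(h$right_start - h$left_end, h$loop_len)
    # right arm is the reverse complement of the left arm up to the
    # reported mismatches
    for (j in seq_len(nrow(h))) {
      left <- substr(s, h$left_start[j] + 1, h$left_end[j])
      right <- substr(s, h$right_start[j] + 1, h$right_end[j])
      mm <- sum(strsplit(dna_revcomp(left), "")[[1]] != strsplit(right, "")[[1]])
      expect_equal(mm, h$mismatches[j])
    }
  }
})

test_that("rotating a circular genome preserves the hit multiset", {
  sg <- generate_genome(synth_config(
    length = 8000, seed = 31, genes = placozoan_gene_template()[1:8, ],
    tandem_plan = NULL,
    sir_plan = tibble::tibble(hexamer = "GGCGCC", count = 6L,
                              stem_min = 6L, stem_max = 9L,
                              loop_min = 0L, loop_max = 2L,
                              mismatch = 1L, region = "intergenic")
  ))
  base <- find_palindromes(sg$genome)
  sig <- function(h) sort(paste(h$stem_len, h$loop_len, h$mismatches, h$hexamer))
  for (off in c(1L, 1234L, 7999L)) {
    rot <- find_palindromes(rotate_genome(sg$genome, off))
    expect_identical(sig(rot), sig(base))
  }
})

test_that("scanning the reverse complement preserves the hit population", {
  # a hairpin is its own reverse complement (up to mismatched pairs), so at
  # zero mismatches the class multiset is identical on both strands; with a
  # mismatch budget the hit count is still preserved
  set.seed(77)
  for (i in 1:3) {
    s <- random_dna(1200)
    fwd0 <- find_palindromes(s, palindrome_params(max_mismatch = 0))
    rev0 <- find_palindromes(dna_revcomp(s), palindrome_params(max_mismatch = 0))
    expect_identical(sort(fwd0$hexamer), sort(rev0$hexamer))
    expect_identical(sort(fwd0$stem_len), sort(rev0$stem_len))
    fwd1 <- find_palindromes(s)
    rev1 <- find_palindromes(dna_revcomp(s))
    expect_equal(nrow(fwd1), nrow(rev1))
  }
})

test_that("raising the mismatch or loop budget never shrinks hit coverage", {
  set.seed(88)
  coverage_bp <- function(h, n) {
    cov <- rep(FALSE, n)
    for (j in seq_len(nrow(h))) {
      cov[(h$left_start[j]:(h$right_end[j] - 1)) %% n + 1] <- TRUE
    }
    sum(cov)
  }
  for (i in 1:3) {
    s <- random_dna(1000)
    n <- nchar(s)
    c0 <- coverage_bp(find_palindromes(s, palindrome_params(max_mismatch = 0)), n)
    c1 <- coverage_bp(find_palindromes(s, palindrome_params(max_mismatch = 1)), n)
    expect_gte(c1, c0)
    l5 <- coverage_bp(find_palindromes(s, palindrome_params(max_loop = 5)), n)
    l10 <- coverage_bp(find_palindromes(s, palindrome_params(max_loop = 10)), n)
    expect_gte(l10, l5)
  }
})

test_that("N bases never pair and ambiguous stems are excluded from tables", {
  h <- find_palindromes("AGGCGCNTTTNGCGCCA", palindrome_params(max_mismatch = 0))
  expect_false(any(h$stem_len >= 6))
  sN <- paste0("T", "GGNGCC", "AA", "GGCNCC", "T")
  hN <- find_palindromes(sN, palindrome_params(max_mismatch = 1))
  if (nrow(hN) > 0) {
    expect_true(all(hN$hexamer %in% "ambiguous" | !grepl("N", hN$hexamer)))
    expect_equal(nrow(call_repeat_types(hN, threshold = 1)),
                 nrow(hN[hN$hexamer != "ambiguous", ]))
  }
})

test_that("cohort SIR tables follow the union-roster logic and conserve totals", {
  # genome A: 12 GGCGCC plants; genome B: 2 GGCGCC plants (below threshold)
  mk <- function(count, seed, id) {
    generate_genome(synth_config(
      length = 12000, id = id, seed = seed,
      genes = placozoan_gene_template()[1:10, ], tandem_plan = NULL,
      sir_plan = tibble::tibble(hexamer = "GGCGCC", count = count,
                                stem_min = 8L, stem_max = 10L,
                                loop_min = 0L, loop_max = 2L,
                                mismatch = 1L, region = "intergenic")
    ))
  }
  ga <- mk(12L, 61, "gA")
  gb <- mk(2L, 62, "gB")
  pa <- partition_regions(ga$genome, ga$features)
  pb <- partition_regions(gb$genome, gb$features)
  ha <- scan_sirs(ga$genome, partition = pa)$hits
  hb <- scan_sirs(gb$genome, partition = pb)$hits
  tab <- build_sir_tables(list(gA = ha, gB = hb),
                          partitions = list(gA = pa, gB = pb),
                          roster_scope = "union")
  expect_true("GGCGCC" %in% tab$roster)
  ca <- tab$counts[tab$counts$genome_id == "gA" & tab$counts$hexamer == "GGCGCC", ]
  cb <- tab$counts[tab$counts$genome_id == "gB" & tab$counts$hexamer == "GGCGCC", ]
  expect_gte(ca$n, 12L)
  expect_gte(cb$n, 2L)
  # region splits sum to totals for every genome
  expect_equal(tab$totals$n_cr + tab$totals$n_igr, tab$totals$n_total)
  expect_equal(tab$totals$bp_cr + tab$totals$bp_igr, tab$totals$bp_total)
  # per-genome scope drops classes below each genome's own threshold
  tab_pg <- build_sir_tables(list(gA = ha, gB = hb),
                             partitions = list(gA = pa, gB = pb),
                             roster_scope = "per_genome")
  expect_false("GGCGCC" %in%
                 tab_pg$counts$hexamer[tab_pg$counts$genome_id == "gB"])
})

test_that("planted SIRs in the intended region class are tallied there", {
  sg <- generate_genome(synth_config(
    length = 26000, seed = 71, tandem_plan = NULL,
    sir_plan = tibble::tibble(
      hexamer = c("GGCGCC", "GGTACC"), count = c(10L, 10L),
      stem_min = 7L, stem_max = 9L, loop_min = 0L, loop_max = 2L,
      mismatch = 1L, region = c("intergenic", "coding")
    )
  ))
  part <- partition_regions(sg$genome, sg$features)
  hits <- scan_sirs(sg$genome, partition = part)$hits
  tr <- sg$truth$sirs
  m <- match(paste(tr$left_start, tr$right_end),
             paste(hits$left_start, hits$right_end))
  expect_false(anyNA(m))
  expect_equal(unname(hits$region[m]), unname(tr$region))
})
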
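empty_features_for_tests <- function() {
  features(character(), character(), integer(), integer(),
           strand = character(), feature_id = integer(), part = integer())
}

minimal_gb <- function(seq, feature_lines, id = "toy", topology = "circular") {
  n <- nchar(seq)
  c(
    sprintf("LOCUS       %s %d bp DNA %s UNA 01-JAN-2026", id, n, topology),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", n)),
    feature_lines,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//"
  )
}

test_that("GenBank 1-based inclusive locations map to 0-based half-open", {
  seq <- strrep("ACGT", 25)
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, c(
    "     CDS             11..40",
    "                     /gene=\"geneA\""
  )), tf)
  rec <- read_genbank(tf)
  expect_equal(genome_length(rec$genome), 100L)
  expect_equal(rec$genome$topology, "circular")
  expect_equal(nrow(rec$features), 1L)
  expect_equal(rec$features$start, 10L)
  expect_equal(rec$features$end, 40L)
  expect_equal(rec$features$strand, "+")
  expect_equal(rec$features$label, "geneA")
})

test_that("origin-wrapping complement(join()) becomes one two-part minus feature", {
  seq <- strrep("ACGT", 25)
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, c(
    "     CDS             complement(join(90..100,1..10))",
    "                     /gene=\"wrapper\""
  )), tf)
  rec <- read_genbank(tf)
  f <- rec$features
  expect_equal(length(unique(f$feature_id)), 1L)
  expect_equal(nrow(f), 2L)
  expect_true(all(f$strand == "-"))
  expect_equal(sum(f$end - f$start), 21L)
  # parts ordered along transcription: minus strand starts at the
  # genomically later segment
  expect_equal(f$start[f$part == 1], 0L)
  expect_equal(f$end[f$part == 1], 10L)
  expect_equal(f$start[f$part == 2], 89L)
})

test_that("missing sequence is an error; bad features are skipped with a warning", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       x 10 bp DNA linear", "FEATURES", "ORIGIN", "//"), tf)
  expect_error(read_genbank(tf), "empty sequence")
  tf2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(minimal_gb(strrep("ACGT", 25), c(
    "     CDS             11..999",
    "                     /gene=\"broken\"",
    "     tRNA            5..10",
    "                     /gene=\"trnX\""
  )), tf2)
  expect_warning(rec <- read_genbank(tf2), "skipping")
  expect_equal(rec$features$label, "trnX")
})

test_that("generator output round-trips through GenBank identically", {
  sg <- generate_genome(synth_config(seed = 11))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sg$genome, sg$features, tf)
  rt <- read_genbank(tf)
  expect_identical(rt$genome$sequence, sg$genome$sequence)
  expect_identical(rt$genome$topology, "circular")
  cols <- c("label", "kind", "strand", "start", "end", "part")
  expect_equal(
    as.data.frame(rt$features)[cols],
    as.data.frame(sg$features)[cols],
    ignore_attr = TRUE
  )
})

test_that("region partition conserves genome length and honours truth totals", {
  g <- circular_genome(strrep("ACGT", 250), "toy")
  f <- features("geneA", "protein_gene", 100, 400)
  p <- partition_regions(g, f)
  expect_equal(unname(p$sizes[["coding"]]), 300)
  expect_equal(unname(p$sizes[["intergenic"]]), 700)
  expect_equal(sum(p$sizes[c("coding", "intergenic")]), 1000)

  p0 <- partition_regions(g, empty_features_for_tests())
  expect_equal(unname(p0$sizes[["coding"]]), 0)
  expect_equal(unname(p0$sizes[["intergenic"]]), 1000)

  sg <- generate_genome(synth_config(seed = 5))
  part <- partition_regions(sg$genome, sg$features)
  tmpl <- placozoan_gene_template()
  coding_kinds <- c("protein_gene", "rRNA", "tRNA", "orf_unknown", "exon")
  expect_equal(unname(part$sizes[["coding"]]),
               sum(tmpl$length[tmpl$kind %in% coding_kinds]))
  expect_equal(unname(part$sizes[["intronI"]]),
               sum(tmpl$length[tmpl$kind == "intron_groupI"]))
  expect_equal(unname(part$sizes[["intronII"]]),
               sum(tmpl$length[tmpl$kind == "intron_groupII"]))
  expect_equal(sum(part$sizes[c("coding", "intergenic")]),
               genome_length(sg$genome))
})

test_that("gene-order extraction drops ORFs/introns and suffixes duplicates", {
  f <- features(
    label = c("a", "orfX", "b", "c"),
    kind = c("tRNA", "orf_unknown", "protein_gene", "rRNA"),
    start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    strand = c("+", "+", "-", "+")
  )
  go <- extract_gene_order(f)
  expect_equal(go$label, c("a", "b", "c"))
  expect_equal(go$strand, c("+", "-", "+"))

  expect_equal(nrow(extract_gene_order(empty_features_for_tests())), 0L)

  fdup <- features(c("x", "x"), c("tRNA", "tRNA"), c(0, 100), c(50, 150))
  expect_message(go2 <- extract_gene_order(fdup), "duplicate")
  expect_equal(go2$label, c("x_1", "x_2"))
})

test_that("gene order is invariant under rotation of the record start", {
  sg <- generate_genome(synth_config(length = 20000, seed = 13,
                                     sir_plan = NULL, tandem_plan = NULL))
  base <- extract_gene_order(sg$features, genome_id = "base")
  n <- genome_length(sg$genome)
  for (off in c(137L, 9000L, 19999L)) {
    feats_rot <- mitosir:::rotate_features(sg$features, off, n)
    rot <- extract_gene_order(feats_rot, genome_id = "rot")
    expect_equal(breakpoint_distance(base, rot), 0L)
  }
})

test_that("coordinate conversion round-trips through the GenBank writer", {
  # random interval sets survive write -> read unchanged
  set.seed(20)
  n <- 5000L
  starts <- sort(sample(0:(n - 200L), 8))
  f <- features(
    label = paste0("u", seq_along(starts)),
    kind = sample(c("protein_gene", "tRNA", "rRNA"), 8, TRUE),
    start = starts, end = starts + sample(50:150, 8, TRUE),
    strand = sample(c("+", "-"), 8, TRUE)
  )
  g <- circular_genome(random_dna(n), "conv")
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, f, tf)
  rt <- read_genbank(tf)
  cols <- c("label", "kind", "strand", "start", "end")
  expect_equal(as.data.frame(rt$features)[cols], as.data.frame(f)[cols],
               ignore_attr = TRUE)
})
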
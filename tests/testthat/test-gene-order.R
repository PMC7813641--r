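mk_order <- function(labels, strands, id) {
  mitosir:::new_gene_order(
    tibble::tibble(position = seq_along(labels), label = labels, strand = strands),
    id
  )
}

test_that("two identical circular orders collapse to one section", {
  o1 <- mk_order(c("a", "b", "c"), c("+", "+", "+"), "g1")
  o2 <- mk_order(c("a", "b", "c"), c("+", "+", "+"), "g2")
  ss <- merge_sections(list(g1 = o1, g2 = o2))
  expect_equal(glance(ss)$n_sections, 1L)
  expect_setequal(ss$sections$label, c("a", "b", "c"))
  so <- section_order(o1, ss)
  expect_equal(nrow(so), 1L)
  expect_equal(so$orientation, "+")
})

test_that("an orientation flip isolates the flipped unit", {
  o1 <- mk_order(c("a", "b", "c", "d"), c("+", "+", "+", "+"), "g1")
  o2 <- mk_order(c("a", "b", "c", "d"), c("+", "-", "+", "+"), "g2")
  ss <- merge_sections(list(g1 = o1, g2 = o2))
  g <- glance(ss)
  expect_equal(g$n_sections, 2L)
  expect_equal(g$n_singleton, 1L)
  secs <- split(ss$sections$label, ss$sections$section)
  sizes <- vapply(secs, length, integer(1))
  expect_setequal(secs[[names(sizes)[sizes == 1]]], "b")
  expect_setequal(secs[[names(sizes)[sizes == 3]]], c("c", "d", "a"))
  # brute-force adjacency-conservation oracle agrees
  exp_groups <- lapply(secs, sort)
  exp_groups <- unname(exp_groups[order(vapply(exp_groups, `[`, character(1), 1))])
  expect_equal(oracle_sections(list(o1, o2)), exp_groups, ignore_attr = TRUE)
})

test_that("signed reversal counts as the same adjacency", {
  # -b,-a in one genome matches +a,+b in another
  o1 <- mk_order(c("a", "b", "x"), c("+", "+", "+"), "g1")
  o2 <- mk_order(c("b", "a", "x"), c("-", "-", "+"), "g2")
  ss <- merge_sections(list(g1 = o1, g2 = o2))
  secs <- split(ss$sections$label, ss$sections$section)
  expect_true(any(vapply(secs, function(s) setequal(s, c("a", "b")), logical(1))))
})

test_that("units private to one genome become singletons that do not block merging", {
  o1 <- mk_order(c("a", "b", "c", "z"), c("+", "+", "+", "+"), "g1")
  o2 <- mk_order(c("a", "b", "c"), c("+", "+", "+"), "g2")
  ss <- merge_sections(list(g1 = o1, g2 = o2))
  secs <- split(ss$sections$label, ss$sections$section)
  # a-b and b-c conserved; c-a broken in g1 by z; z is singleton
  expect_true(any(vapply(secs, function(s) setequal(s, c("a", "b", "c")), logical(1))))
  expect_true(any(vapply(secs, function(s) identical(s, "z"), logical(1))))
})

test_that("section orders flag inverted blocks with negative orientation", {
  sg <- generate_genome(synth_config(length = 22000, seed = 17,
                                     sir_plan = NULL, tandem_plan = NULL))
  tree <- ape::read.tree(text = "((t1,t2),t3);")
  plan <- tibble::tibble(node = "t1", type = "inversion",
                         from_unit = "cox2", to_unit = "atp6",
                         after_unit = NA_character_)
  coh <- evolve_along_tree(sg, tree, plan)
  orders <- lapply(coh$tips, function(x)
    extract_gene_order(x$features, genome_id = x$genome$id))
  ss <- merge_sections(orders)
  so1 <- section_order(orders$t1, ss)
  so2 <- section_order(orders$t2, ss)
  expect_equal(sort(so1$section), sort(so2$section))
  flipped <- so1$section[so1$orientation != so2$orientation[match(so1$section, so2$section)]]
  expect_equal(length(flipped), 1L)
  # the flipped section is the inverted block
  blk <- ss$sections$label[ss$sections$section == flipped]
  expect_true(all(c("cox2", "atp6") %in% blk))
})

test_that("breakpoint distance equals the direct adjacency-set oracle", {
  o1 <- mk_order(letters[1:6], rep("+", 6), "g1")
  expect_equal(breakpoint_distance(o1, o1), 0L)
  # single internal block inversion -> distance 2
  o_inv <- mk_order(c("a", "d", "c", "b", "e", "f"),
                    c("+", "-", "-", "-", "+", "+"), "g2")
  expect_equal(breakpoint_distance(o1, o_inv), 2L)
  expect_equal(breakpoint_distance(o_inv, o1), 2L)

  set.seed(91)
  for (i in 1:25) {
    k <- sample(4:9, 1)
    labs <- letters[1:k]
    p1 <- sample(labs)
    s1 <- sample(c("+", "-"), k, TRUE)
    p2 <- sample(labs)
    s2 <- sample(c("+", "-"), k, TRUE)
    a <- mk_order(p1, s1, "A")
    b <- mk_order(p2, s2, "B")
    expect_equal(
      breakpoint_distance(a, b),
      oracle_breakpoints(p1, ifelse(s1 == "+", 1L, -1L),
                         p2, ifelse(s2 == "+", 1L, -1L))
    )
    expect_equal(breakpoint_distance(a, b), breakpoint_distance(b, a))
    expect_equal(breakpoint_distance(a, a), 0L)
  }
  expect_error(breakpoint_distance(mk_order("a", "+", "x"), o1), "fewer than 2")
})

test_that("adding a genome can only split sections, never merge them", {
  set.seed(95)
  o1 <- mk_order(letters[1:8], rep("+", 8), "g1")
  o2 <- mk_order(c("a", "b", "c", "d", "f", "e", "g", "h"),
                 c(rep("+", 4), "-", "-", "+", "+"), "g2")
  o3 <- mk_order(c("c", "d", "a", "b", "e", "f", "g", "h"),
                 rep("+", 8), "g3")
  memb <- function(ss) {
    secs <- split(ss$sections$label, ss$sections$section)
    lapply(secs, sort)
  }
  two <- memb(merge_sections(list(g1 = o1, g2 = o2)))
  three <- memb(merge_sections(list(g1 = o1, g2 = o2, g3 = o3)))
  # each section of the larger cohort is inside one section of the smaller
  for (s in three) {
    expect_true(any(vapply(two, function(t) all(s %in% t), logical(1))))
  }
})

test_that("merge_sections is invariant to input order and rotations", {
  sg <- generate_genome(synth_config(length = 22000, seed = 23,
                                     sir_plan = NULL, tandem_plan = NULL))
  tree <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  plan <- tibble::tibble(
    node = c("t1", "t3"), type = c("inversion", "translocation"),
    from_unit = c("nad2", "cob"), to_unit = c("nad4", "nad1"),
    after_unit = c(NA, "trnM")
  )
  coh <- evolve_along_tree(sg, tree, plan)
  orders <- lapply(coh$tips, function(x)
    extract_gene_order(x$features, genome_id = x$genome$id))
  memb <- function(ss) {
    unname(lapply(split(ss$sections$label, ss$sections$section), sort))
  }
  base <- memb(merge_sections(orders))
  perm <- memb(merge_sections(orders[c(3, 1, 4, 2)]))
  expect_setequal(vapply(base, paste, character(1), collapse = "|"),
                  vapply(perm, paste, character(1), collapse = "|"))
  rot <- orders
  tb <- tibble::as_tibble(rot$t2)
  tb <- tb[c(5:nrow(tb), 1:4), ]
  tb$position <- seq_len(nrow(tb))
  rot$t2 <- mitosir:::new_gene_order(tb, "t2")
  rotated <- memb(merge_sections(rot))
  expect_setequal(vapply(base, paste, character(1), collapse = "|"),
                  vapply(rotated, paste, character(1), collapse = "|"))
})

test_that("changes map to the correct tree edge", {
  o_ref <- mk_order(letters[1:6], rep("+", 6), "ref")
  o_inv <- mk_order(c("a", "d", "c", "b", "e", "f"),
                    c("+", "-", "-", "-", "+", "+"), "inv")
  orders <- list(t1 = o_inv, t2 = o_ref, t3 = o_ref)
  ch <- map_events_on_tree(orders, "((t1,t2),t3);")
  t1_row <- ch[ch$node_label == "t1", ]
  expect_equal(t1_row$n_gained, 2L)
  expect_equal(t1_row$n_lost, 2L)
  other <- ch[ch$node_label != "t1", ]
  expect_true(all(other$n_gained + other$n_lost == 0L))

  # identical tips -> empty change list
  ch0 <- map_events_on_tree(list(t1 = o_ref, t2 = o_ref, t3 = o_ref),
                            "((t1,t2),t3);")
  expect_true(all(ch0$n_gained + ch0$n_lost == 0L))
})

test_that("simulated clade events appear on their true edges", {
  sg <- generate_genome(synth_config(length = 22000, seed = 29,
                                     sir_plan = NULL, tandem_plan = NULL))
  tree <- ape::read.tree(text = "((t1,t2)n12,(t3,(t4,t5)n45)n345);")
  plan <- tibble::tibble(
    node = c("n12", "t4"), type = c("inversion", "inversion"),
    from_unit = c("cox2", "12S"), to_unit = c("atp6", "nad6"),
    after_unit = NA_character_
  )
  coh <- evolve_along_tree(sg, tree, plan)
  orders <- lapply(coh$tips, function(x) x$truth$gene_order)
  ch <- map_events_on_tree(orders, tree)
  changed <- ch[ch$n_gained + ch$n_lost > 0, ]
  # the event below the root also mirrors on the sibling root edge (the two
  # root-child edges describe complementary bipartitions)
  expect_true(all(c("n12", "t4") %in% changed$node_label))
  expect_true(all(changed$node_label %in% c("n12", "n345", "t4")))
})
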
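# Gene-order canonicalization, breakpoints, arrangement classes, events.

test_that("canonicalization anchors cox1 forward and is idempotent", {
  sig <- extractGeneOrder(hatraGeneTable())
  can <- canonicalizeOrder(sig)
  o <- orderTable(can)
  expect_equal(o$name[1:3], c("cox1", "trnR", "nad4l"))
  expect_equal(o$strand[1], "+")
  expect_identical(orderTable(canonicalizeOrder(can)), o)
  # rotated input canonicalizes to the same order
  rot <- GeneOrder(c(o$name[10:37], o$name[1:9]),
                   c(o$strand[10:37], o$strand[1:9]), label = "rot")
  expect_identical(orderTable(canonicalizeOrder(rot)), o)
})

test_that("a minus-strand anchor flips the whole reading", {
  # 5-gene hand construction: mirror of (cox1+, a+, b-, c+, d+)
  toy <- GeneOrder(c("d", "c", "b", "a", "cox1"),
                   c("-", "-", "+", "-", "-"), label = "flipped")
  can <- canonicalizeOrder(toy)
  expect_equal(orderTable(can)$name, c("cox1", "a", "b", "c", "d"))
  expect_equal(orderTable(can)$strand, c("+", "+", "-", "+", "+"))
  # anchor must be unique
  expect_error(canonicalizeOrder(GeneOrder(c("a", "b"), "+")), "cox1")
  expect_error(canonicalizeOrder(GeneOrder(c("cox1", "cox1"), "+")), "cox1")
})

test_that("adjacency sets are rotation- and mirror-invariant", {
  g <- GeneOrder(c("cox1", "a", "b", "c"), c("+", "+", "-", "+"))
  rot <- GeneOrder(c("b", "c", "cox1", "a"), c("-", "+", "+", "+"))
  mir <- GeneOrder(c("c", "b", "a", "cox1"), c("-", "+", "-", "-"))
  expect_setequal(adjacencySet(rot), adjacencySet(g))
  expect_setequal(adjacencySet(mir), adjacencySet(g))
})

test_that("breakpoint distance: identity, toy swap, mirrored circle", {
  g <- extractGeneOrder(hatraGeneTable())
  expect_equal(breakpointDistance(g, g), 0L)
  a <- GeneOrder(c("cox1", "g2", "g3", "g4", "g5"), "+")
  b <- GeneOrder(c("cox1", "g3", "g2", "g4", "g5"), "+")
  # brute-force adjacency enumeration: a has {1-2,2-3,3-4,4-5,5-1},
  # b has {1-3,3-2,2-4,4-5,5-1}; 4-5 and 5-1 survive, and the signed pair
  # g3>g2 in b equals the mirror of g2>g3 in a, so 3 adjacencies break
  expect_equal(breakpointDistance(a, b), 3L)
  o <- orderTable(g)
  mirrored <- GeneOrder(rev(o$name),
                        ifelse(rev(o$strand) == "+", "-", "+"),
                        label = "mirror")
  expect_equal(breakpointDistance(g, mirrored), 0L)
})

test_that("unequal gene content restricts with a warning; disjoint errors", {
  a <- GeneOrder(c("cox1", "a", "b", "c"), "+")
  b <- GeneOrder(c("cox1", "a", "c"), "+")
  expect_warning(d <- breakpointDistance(a, b), "restricting")
  expect_equal(d, 0L)  # removing b leaves the same circle
  expect_error(suppressWarnings(
    breakpointDistance(GeneOrder("x", "+"), GeneOrder("y", "+"))),
    "no genes")
})

test_that("arrangement grouping collapses identical canonical orders", {
  g <- extractGeneOrder(hatraGeneTable())
  o <- orderTable(g)
  dup <- GeneOrder(o$name, o$strand, label = "dup")
  moved <- GeneOrder(c(o$name[-29][1:10], o$name[29], o$name[-29][-(1:10)]),
                     c(o$strand[-29][1:10], o$strand[29],
                       o$strand[-29][-(1:10)]), label = "moved")
  grp <- groupArrangements(list(g, dup, moved))
  expect_equal(grp$n_classes, 2L)
  expect_setequal(grp$classes[[1]], c("PV998923", "dup"))
  expect_equal(groupArrangements(list(g, dup))$n_classes, 1L)
})

test_that("event classification identifies the three rearrangement kinds", {
  g <- extractGeneOrder(hatraGeneTable())
  o <- orderTable(canonicalizeOrder(g))
  # single-gene translocation of trnM
  i <- which(o$name == "trnM")
  moved <- rbind(o[-i, ][1:5, ], o[i, ], o[-i, ][-(1:5), ])
  b1 <- GeneOrder(moved$name, moved$strand, label = "trnM-moved")
  ev1 <- classifyEvents(g, b1)
  expect_length(ev1, 1L)
  expect_equal(ev1[[1]]$kind, "single_gene_translocation")
  expect_equal(ev1[[1]]$genes, "trnM")
  # inversion of everything but the anchor
  inv <- rbind(o[1, ], data.frame(name = rev(o$name[-1]),
                                  strand = ifelse(rev(o$strand[-1]) == "+",
                                                  "-", "+")))
  b2 <- GeneOrder(inv$name, inv$strand, label = "all-but-cox1-inverted")
  ev2 <- classifyEvents(g, b2)
  expect_equal(ev2[[1]]$kind, "inversion")
  expect_length(ev2[[1]]$genes, 36L)
  # contiguous multi-gene shift
  blk <- 5:7
  shifted <- rbind(o[-blk, ][1:20, ], o[blk, ], o[-blk, ][-(1:20), ])
  b3 <- GeneOrder(shifted$name, shifted$strand, label = "block-shift")
  ev3 <- classifyEvents(g, b3)
  expect_equal(ev3[[1]]$kind, "multi_gene_shift")
  expect_equal(ev3[[1]]$genes, o$name[blk])
  # identical orders produce no events
  expect_length(classifyEvents(g, g), 0L)
  expect_error(classifyEvents(g, GeneOrder(c("cox1", "zz"), "+")),
               "gene content")
})

test_that("classified events replay to the target order", {
  a <- GeneOrder(c("cox1", "g2", "g3", "g4", "g5", "g6"), "+")
  targets <- list(
    GeneOrder(c("cox1", "g3", "g4", "g2", "g5", "g6"), "+"),     # move g2
    GeneOrder(c("cox1", "g2", "g5", "g4", "g3", "g6"),
              c("+", "+", "-", "-", "-", "+")),                  # invert 3:5
    GeneOrder(c("cox1", "g4", "g5", "g2", "g3", "g6"), "+")      # shift block
  )
  for (b in targets) {
    evs <- classifyEvents(a, b)
    expect_length(evs, 1L)
    expect_false(evs[[1]]$kind == "unclassified")
    replayed <- applyEvent(a, evs[[1]])
    expect_equal(breakpointDistance(replayed, b), 0L)
  }
  # a composite history falls through to unclassified with breakpoints
  comp <- GeneOrder(c("cox1", "g3", "g2", "g5", "g4", "g6"), "+")
  evc <- classifyEvents(a, comp)
  expect_equal(evc[[1]]$kind, "unclassified")
  expect_gt(evc[[1]]$breakpoints, 0L)
})

test_that("database gene-name spellings normalize to the vocabulary", {
  expect_equal(normalizeGeneNames(c("COI", "ND4L", "16S", "trnL(UAG)",
                                    "trnS(tga)", "cox1")),
               c("cox1", "nad4l", "rrnL", "trnL1", "trnS2", "cox1"))
  # custom override map
  map <- data.frame(from = "weird", to = "cox2")
  expect_equal(normalizeGeneNames("WEIRD", map), "cox2")
})

test_that("order diagrams render one labelled line per arrangement", {
  g <- extractGeneOrder(hatraGeneTable())
  lines <- orderDiagram(list(g))
  expect_length(lines, 1L)
  expect_match(lines, "^PV998923\\s+cox1 trnR nad4l")
  expect_match(lines, "-nad6")
})
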
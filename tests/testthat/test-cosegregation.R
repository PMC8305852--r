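test_that("gene origin comes from the block containing its midpoint", {
  blocks <- data.frame(line = "L1", chrom = "A03",
                       start = c(12929867, 23300000),
                       end = c(23248122, 25000000),
                       label = c("P1", "P2"), n_markers = c(3716, 100),
                       n_discordant = c(0, 0))
  gene <- list(chrom = "A03", start = 21326869, stop = 21328218)  # inside P1
  a <- assign_gene_origin(blocks, gene)
  expect_equal(a$label, "P1")
  expect_false(a$boundary)
  # midpoint in a gap between blocks -> NA
  gap_gene <- list(chrom = "A03", start = 23250000, stop = 23260000)
  expect_true(is.na(assign_gene_origin(blocks, gap_gene)$label))
  # gene spanning a breakpoint with midpoint in P1 -> P1 + boundary flag
  two <- data.frame(line = "L1", chrom = "A01", start = c(1, 1001),
                    end = c(1000, 2000), label = c("P1", "P2"),
                    n_markers = c(10, 10), n_discordant = c(0, 0))
  span <- list(chrom = "A01", start = 900, stop = 1100)
  a2 <- assign_gene_origin(two, span)
  expect_equal(a2$label, "P1")
  expect_true(a2$boundary)
})

test_that("gene matrix round-trips blocks built from the packaged table", {
  t3 <- table3_matrix()
  genes <- t3$genes
  lines <- c(HGSL, LGSL)
  # per-line blocks constructed from the transcribed labels: one block per
  # gene interval, coalesced when adjacent genes on a chromosome agree
  blk <- do.call(rbind, lapply(lines, function(ln) {
    g <- genes[order(genes$chrom, genes$start), ]
    lab <- t3$labels[order(genes$chrom, genes$start), ln]
    data.frame(line = ln, chrom = g$chrom, start = g$start, end = g$stop,
               label = ifelse(lab == "LP08", "P1", "P2"),
               n_markers = 10, n_discordant = 0)
  }))
  gm <- build_gene_matrix(blk, genes, lines = lines)
  expected <- ifelse(t3$labels[, lines] == "LP08", "P1", "P2")
  expect_identical(unname(gm$labels[, lines]), unname(expected))
})

test_that("matrix with zero lines keeps gene rows; column order follows input", {
  genes <- data.frame(chrom = "A01", start = c(10, 100), stop = c(20, 200),
                      name = c("g1", "g2"))
  blocks <- data.frame(line = character(), chrom = character(),
                       start = integer(), end = integer(),
                       label = character(), n_markers = integer(),
                       n_discordant = integer())
  expect_warning(gm <- build_gene_matrix(blocks, genes, lines = character()),
                 "absent")
  expect_equal(dim(gm$labels), c(2, 0))
  b2 <- data.frame(line = rep(c("La", "Lb"), each = 1), chrom = "A01",
                   start = 1, end = 300, label = c("P1", "P2"),
                   n_markers = 5, n_discordant = 0)
  gm_ab <- build_gene_matrix(b2, genes, lines = c("La", "Lb"))
  gm_ba <- build_gene_matrix(b2, genes, lines = c("Lb", "La"))
  expect_identical(gm_ab$labels[, c("La", "Lb")], gm_ba$labels[, c("La", "Lb")])
})

test_that("the packaged genotype table yields exactly the ten known genes", {
  t3 <- table3_matrix()
  cs <- find_cosegregating_genes(
    structure(list(genes = t3$genes, labels = t3$labels),
              class = "dh_gene_matrix"),
    HGSL, LGSL, parent_labels = c("LP08", "LP21"))
  expect_equal(nrow(cs), 10)
  expect_setequal(cs$gene_id_v1_5,
                  c("Bra012961", "Bra013000", "Bra001761", "Bra013007",
                    "Bra013009", "Bra013011", "Bra000760", "Bra000847",
                    "Bra000848", "Bra013120"))
  expect_true(all(cs$groupA_label == "LP08"))
  expect_true(all(cs$chrom == "A03"))
  expect_true(all(cs$start >= 12929867 & cs$stop <= 23248122))
})

test_that("group contracts: overlap and empties are errors; no separation is empty", {
  t3 <- table3_matrix()
  m <- structure(list(genes = t3$genes, labels = t3$labels),
                 class = "dh_gene_matrix")
  expect_error(find_cosegregating_genes(m, HGSL, c(LGSL, "DH005")), "overlap")
  expect_error(find_cosegregating_genes(m, character(), LGSL), "non-empty")
  allp1 <- matrix("P1", nrow = 3, ncol = 4,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(nrow(find_cosegregating_genes(allp1, c("a", "b"), c("c", "d"))),
               0)
})

test_that("HET or NA cells disqualify a gene from perfect co-segregation", {
  lab <- matrix(c("P1", "P1", "P2", "P2",
                  "P1", "HET", "P2", "P2",
                  "P1", NA, "P2", "P2"),
                nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
  cs <- find_cosegregating_genes(lab, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(cs), 1)
})

test_that("adding a line to a group can only shrink the co-segregating set", {
  t3 <- table3_matrix()
  m <- structure(list(genes = t3$genes, labels = t3$labels),
                 class = "dh_gene_matrix")
  for (k in 1:4) {
    sub <- find_cosegregating_genes(m, HGSL[1:k], LGSL,
                                    parent_labels = c("LP08", "LP21"))
    full <- find_cosegregating_genes(m, HGSL[1:(k + 1)], LGSL,
                                     parent_labels = c("LP08", "LP21"))
    expect_true(all(full$gene_id_v1_5 %in% sub$gene_id_v1_5))
  }
})

test_that("a planted causal region is recovered as a marker-bounded region", {
  cfg <- small_sim(seed = 61, n_lines = 30)
  m <- simulate_markers(cfg)
  truth <- simulate_dh_mosaics(cfg, m)
  obs <- observe_genotypes(truth, m, cfg)
  ph <- simulate_metabolites(truth, cfg)
  g <- attr(ph, "groups")
  blocks <- call_blocks_all(obs$calls, m, hmm_params())
  regions <- find_cosegregating_regions(m, blocks,
                                        g$line[g$group == "high"],
                                        g$line[g$group == "low"])
  expect_equal(nrow(regions), 1)
  # oracle: the truly separating marker run from the simulator's truth labels
  tl <- vapply(truth$lines, function(ln)
    dhblocks:::truth_label_at(truth, ln, "A01", m$pos), character(nrow(m)))
  sep <- rowSums(tl[, g$line[g$group == "high"], drop = FALSE] == "P1") ==
    sum(g$group == "high") &
    rowSums(tl[, g$line[g$group == "low"], drop = FALSE] == "P2") ==
    sum(g$group == "low")
  r <- rle(sep)
  ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
  big <- which(r$values)[which.max(r$lengths[r$values])]
  expect_equal(regions$start, m$pos[starts[big]])
  expect_equal(regions$end, m$pos[ends[big]])
  mid <- (cfg$causal_region$start + cfg$causal_region$end) / 2
  expect_true(regions$start <= mid && regions$end >= mid)
})

test_that("swapping the groups swaps the region labels only", {
  cfg <- small_sim(seed = 67, n_lines = 20)
  m <- simulate_markers(cfg)
  truth <- simulate_dh_mosaics(cfg, m)
  obs <- observe_genotypes(truth, m, cfg)
  ph <- simulate_metabolites(truth, cfg)
  g <- attr(ph, "groups")
  blocks <- call_blocks_all(obs$calls, m, hmm_params())
  hi <- g$line[g$group == "high"]; lo <- g$line[g$group == "low"]
  r1 <- find_cosegregating_regions(m, blocks, hi, lo)
  r2 <- find_cosegregating_regions(m, blocks, lo, hi)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$end, r2$end)
  expect_equal(r1$groupA_label, r2$groupB_label)
})

test_that("pathway profile groups gene labels by stage", {
  t3 <- table3_matrix()
  gm <- structure(list(genes = t3$genes, labels = t3$labels),
                  class = "dh_gene_matrix")
  prof <- pathway_profile(gm, "DH005")
  elong <- prof[prof$stage == "Side chain elongation", ]
  lp08_genes <- strsplit(elong$genes[elong$label == "LP08"], ",")[[1]]
  # the full MAM trio of the A03 region is parent-1 type in DH005
  expect_true(all(c("MAM1", "MAM3") %in% lp08_genes))
  mam_a03 <- t3$labels[t3$genes$gene_id_v1_5 %in%
                         c("Bra013007", "Bra013009", "Bra013011"), "DH005"]
  expect_true(all(mam_a03 == "LP08"))
  # parent column is uniformly its own type
  prof21 <- pathway_profile(gm, "LP21")
  expect_true(all(prof21$label == "LP21"))
  # counts per stage partition the stage's genes
  tot <- tapply(prof$n, prof$stage, sum)
  expected <- table(t3$genes$stage)
  expect_equal(as.numeric(tot[names(expected)]), as.numeric(expected))
  expect_error(pathway_profile(gm, "nope"), "unknown line")
})
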
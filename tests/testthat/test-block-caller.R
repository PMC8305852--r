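test_that("transition matrix is the identity at zero distance", {
  p <- hmm_params()
  expect_equal(transition_matrix(0, p), diag(3),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("transition matrix rows sum to 1 and switch approaches Haldane limit", {
  p <- hmm_params(het_prior = 0.01)
  for (d in c(0, 1e3, 1e5, 1e7, 1e9)) {
    m <- transition_matrix(d, p)
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
  }
  far <- transition_matrix(1e12, p)
  expect_equal(far["P1", "P2"], 0.5 * (1 - p$het_prior), tolerance = 1e-9)
})

test_that("parental switch probability is strictly increasing in distance", {
  p <- hmm_params()
  d <- seq(0, 5e6, length.out = 200)
  r <- vapply(d, function(x) transition_matrix(x, p)["P1", "P2"], numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("unanimous evidence decodes to a constant path", {
  p <- hmm_params()
  v <- viterbi_path(rep("P1", 60), (1:60) * 1e4, p)
  expect_equal(v$path, rep("P1", 60))
})

test_that("a clean 50/50 split decodes to exactly one switch at the boundary", {
  p <- hmm_params()
  calls <- c(rep("P1", 50), rep("P2", 50))
  v <- viterbi_path(calls, (1:100) * 1e4, p)
  expect_equal(v$path, calls)
})

test_that("an isolated discordant call is absorbed", {
  p <- hmm_params()
  calls <- rep("P1", 99)
  calls[50] <- "P2"
  v <- viterbi_path(calls, (1:99) * 1e4, p)
  expect_equal(v$path, rep("P1", 99))
})

test_that("Viterbi matches the exhaustive-path maximum on short sequences", {
  p <- hmm_params()
  for (s in 1:25) {
    x <- random_call_seq(10, seed = s)
    v <- viterbi_path(x$calls, x$positions, p)
    bf <- brute_force_max_logprob(x$calls, x$positions, p)
    expect_equal(v$log_prob, bf, tolerance = 1e-9)
  }
})

test_that("empty call sequence yields an empty path and no blocks", {
  p <- hmm_params()
  v <- viterbi_path(character(), numeric(), p)
  expect_equal(v$path, character())
  expect_equal(nrow(path_to_blocks(character(), numeric(), p)), 0)
})

test_that("single-label path becomes one fully supported block", {
  p <- hmm_params()
  b <- path_to_blocks(rep("P1", 100), (1:100) * 1e3, p)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_markers, 100)
  expect_equal(b$n_discordant, 0)
  expect_equal(b$start, 1e3)
  expect_equal(b$end, 1e5)
})

test_that("small middle block merges into the better supported flank", {
  p <- hmm_params(min_block_markers = 5)
  path <- c(rep("P1", 50), rep("P2", 3), rep("P1", 47))
  b <- path_to_blocks(path, (1:100) * 1e3, p, raw_calls = path)
  expect_equal(nrow(b), 1)
  expect_equal(b$label, "P1")
  expect_equal(b$n_markers, 100)
  expect_equal(b$n_discordant, 3)
})

test_that("small-block merge prefers the left flank on ties", {
  p <- hmm_params(min_block_markers = 5)
  path <- c(rep("P1", 10), rep("HET", 2), rep("P2", 10))
  b <- path_to_blocks(path, (1:22) * 1e3, p, raw_calls = path)
  expect_equal(b$label, c("P1", "P2"))
  expect_equal(b$n_markers, c(12, 10))
})

test_that("MISSING markers do not count as block support or discord", {
  p <- hmm_params(min_block_markers = 1)
  path <- rep("P1", 10)
  raw <- c("P1", "MISSING", "P1", "P2", rep("P1", 5), "MISSING")
  b <- path_to_blocks(path, (1:10) * 1e3, p, raw_calls = raw)
  expect_equal(b$n_markers, 8)
  expect_equal(b$n_discordant, 1)
})

test_that("noiseless lines reproduce truth blocks bounded by their markers", {
  cfg <- small_sim(seed = 51, n_lines = 15, genotype_error_eps = 0,
                   missing_rate = 0)
  m <- simulate_markers(cfg)
  truth <- simulate_dh_mosaics(cfg, m)
  obs <- observe_genotypes(truth, m, cfg)
  # noise-free data is decoded with a matched emission model: the error-rate
  # parameter goes to its noiseless limit and no small-block merge is applied
  blocks <- call_blocks_all(obs$calls, m,
                            hmm_params(eps = 1e-9, min_block_markers = 1))
  for (ln in truth$lines) {
    tl <- dhblocks:::truth_label_at(truth, ln, "A01", m$pos)
    b <- blocks[blocks$line == ln, ]
    # per-marker decoded label equals truth everywhere
    dec <- character(nrow(m))
    for (i in seq_len(nrow(b)))
      dec[m$pos >= b$start[i] & m$pos <= b$end[i]] <- b$label[i]
    expect_identical(dec, tl)
    # every inferred breakpoint sits in the same inter-marker interval as a
    # true crossover: truth label changes across consecutive markers exactly
    # where inferred blocks change
    expect_equal(which(tl[-1] != tl[-length(tl)]),
                 match(b$start[-1], m$pos) - 1)
  }
})

test_that("label swap flips block labels and nothing else", {
  cfg <- small_sim(seed = 53, n_lines = 1)
  m <- simulate_markers(cfg)
  truth <- simulate_dh_mosaics(cfg, m)
  obs <- observe_genotypes(truth, m, cfg)
  calls <- obs$calls[, 1]
  flip <- c(P1 = "P2", P2 = "P1", HET = "HET", MISSING = "MISSING")
  b1 <- call_blocks(calls, m, hmm_params(), line = "x")
  b2 <- call_blocks(unname(flip[calls]), m, hmm_params(), line = "x")
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
  expect_equal(b1$n_markers, b2$n_markers)
  expect_identical(unname(flip[b1$label]), b2$label)
})

test_that("blocks partition all markers and respect run-count bound", {
  cfg <- small_sim(seed = 57, n_lines = 8)
  m <- simulate_markers(cfg)
  truth <- simulate_dh_mosaics(cfg, m)
  obs <- observe_genotypes(truth, m, cfg)
  blocks <- call_blocks_all(obs$calls, m, hmm_params())
  for (ln in truth$lines) {
    b <- blocks[blocks$line == ln, ]
    assigned <- rowSums(outer(m$pos, b$start, ">=") & outer(m$pos, b$end, "<="))
    expect_true(all(assigned == 1))
    expect_true(all(b$label[-1] != b$label[-nrow(b)]) || nrow(b) <= 1)
    raw_runs <- length(rle(obs$calls[obs$calls[, ln] != "MISSING", ln])$lengths)
    expect_lte(nrow(b), max(raw_runs, 1))
  }
})

test_that("a chromosome without markers warns and yields no blocks", {
  m <- data.frame(chrom = character(), pos = integer())
  expect_equal(nrow(call_blocks(character(), m, hmm_params())), 0)
})
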
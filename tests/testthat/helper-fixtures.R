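# Shared helpers: small simulation configs, a hand-written toy VCF, and an
# exhaustive-path HMM oracle independent of the Viterbi implementation.

small_sim <- function(seed = 1, n_lines = 10, len = 2e6, ...) {
  sim_config(chrom_lengths = c(A01 = len), n_dh_lines = n_lines,
             causal_region = list(chrom = "A01", start = floor(len * 0.4),
                                  end = floor(len * 0.6), high_label = "P1"),
             seed = seed, ...)
}

# 6-record toy VCF: 1 het-parent site, 1 multiallelic site, 1 parent-missing
# site, 3 valid differential sites.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=A01>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "LP08", "LP21", "DH1"), collapse = "\t"),
    "A01\t100\t.\tA\tG\t60\tPASS\t.\tGT\t0/0\t1/1\t0/0",
    "A01\t200\t.\tC\tT\t60\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "A01\t300\t.\tG\tA,T\t60\tPASS\t.\tGT\t0/0\t1/1\t2/2",
    "A01\t400\t.\tT\tC\t60\tPASS\t.\tGT\t./.\t1/1\t1/1",
    "A01\t500\t.\tA\tAT\t60\tPASS\t.\tGT\t1/1\t0/0\t0/1",
    "A01\t600\t.\tG\tC\t60\tPASS\t.\tGT\t0/0\t1/1\t1/1")
  writeLines(lines, path)
  path
}

# Exhaustive joint-probability maximum over all 3^n state paths, evaluated by
# carrying every path prefix's probability forward as a vector (no per-state
# maximisation anywhere, so it is independent of the Viterbi recursion).
brute_force_max_logprob <- function(calls, positions, params) {
  states <- c("P1", "P2", "HET")
  n <- length(calls)
  h <- params$het_prior
  init <- log(c((1 - h) / 2, (1 - h) / 2, max(h, 1e-300)))
  emis <- function(call) {
    if (call == "MISSING") return(c(0, 0, 0))
    lp <- rep(log(params$eps / 2), 3)
    lp[match(call, states)] <- log(1 - params$eps)
    lp
  }
  lp <- init + emis(calls[1])     # length 3: prob per length-1 path
  last <- 1:3                     # last state of each enumerated path
  if (n > 1) {
    for (t in 2:n) {
      lt <- log(transition_matrix(positions[t] - positions[t - 1], params))
      e <- emis(calls[t])
      lp <- as.vector(vapply(1:3, function(s) lp + lt[last, s] + e[s],
                             numeric(length(lp))))
      last <- rep(1:3, each = length(last))
    }
  }
  max(lp)
}

random_call_seq <- function(n, seed) {
  set.seed(seed)
  calls <- sample(c("P1", "P2", "HET", "MISSING"), n, replace = TRUE,
                  prob = c(0.45, 0.45, 0.05, 0.05))
  positions <- sort(sample.int(1e6, n))
  list(calls = calls, positions = positions)
}

table3_matrix <- function() {
  m3 <- read.csv(dhblocks_fixture("table3_matrix.csv"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  cols <- c("LP08", "DH005", "DH014", "DH016", "DH017", "DH026",
            "DH009", "DH059", "DH061", "LP21")
  list(genes = m3[, setdiff(names(m3), cols)],
       labels = as.matrix(m3[, cols]))
}

HGSL <- c("DH005", "DH014", "DH016", "DH017", "DH026")
LGSL <- c("DH009", "DH059", "DH061")
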
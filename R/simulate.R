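#' Simulation configuration for a biparental DH population
#'
#' Bundles every parameter of the synthetic-data generator: a genome, marker
#' density, population size, meiotic and observational noise, and a causal
#' region that links parental origin to a quantitative metabolite phenotype.
#' Defaults emulate the study conditions of a high- vs low-glucosinolate
#' *Brassica rapa* DH cross: a high phenotype regime around 50 units
#' (observed range roughly 44-57) and a low regime around 7 (roughly 3-11),
#' with the dominant compound carrying ~85% of the total.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length (bp).
#' @param marker_density expected parent-informative markers per bp
#'   (default 1e-4, i.e. one per 10 kb).
#' @param n_dh_lines number of DH lines to simulate.
#' @param crossover_rate_lambda Poisson mean crossovers per chromosome per
#'   line (default 2).
#' @param genotype_error_eps probability a marker call is replaced by a wrong
#'   label (default 0.02).
#' @param missing_rate probability a marker call is MISSING (default 0.01).
#' @param residual_het_rate probability a true segment is heterozygous
#'   (default 0; ideal DH lines are fully homozygous).
#' @param causal_region list with elements `chrom`, `start`, `end`,
#'   `high_label` ("P1" or "P2"): parental origin here sets the phenotype
#'   regime.
#' @param phenotype_params list with `mean_high`, `sd_high`, `mean_low`,
#'   `sd_low` (defaults 50, 5, 7, 2).
#' @param compound_fractions named numeric vector splitting each line's total
#'   into component compounds; must sum to 1.  Default is a gluconapin-
#'   dominant profile (GNA fraction 0.85).
#' @param n_replicates biological replicates per line (default 3).
#' @param seed integer root seed; fully determines all generator output.
#' @return an object of class `dh_sim_config` (a validated list).
#' @export
sim_config <- function(chrom_lengths,
                       marker_density = 1e-4,
                       n_dh_lines = 50,
                       crossover_rate_lambda = 2,
                       genotype_error_eps = 0.02,
                       missing_rate = 0.01,
                       residual_het_rate = 0,
                       causal_region = NULL,
                       phenotype_params = list(mean_high = 50, sd_high = 5,
                                               mean_low = 7, sd_low = 2),
                       compound_fractions = c(GNA = 0.85, GBN = 0.05,
                                              GAL = 0.04, GRA = 0.02,
                                              NGBS = 0.02, GNT = 0.01,
                                              PRO = 0.01),
                       n_replicates = 3,
                       seed = 1L) {
  cfg <- structure(
    list(chrom_lengths = chrom_lengths, marker_density = marker_density,
         n_dh_lines = n_dh_lines,
         crossover_rate_lambda = crossover_rate_lambda,
         genotype_error_eps = genotype_error_eps,
         missing_rate = missing_rate,
         residual_het_rate = residual_het_rate,
         causal_region = causal_region,
         phenotype_params = phenotype_params,
         compound_fractions = compound_fractions,
         n_replicates = n_replicates,
         seed = as.integer(seed)),
    class = "dh_sim_config")
  errs <- validate_sim_config(cfg)
  if (length(errs)) stopf("invalid simulation config:\n- %s",
                          paste(errs, collapse = "\n- "))
  cfg
}

validate_sim_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(length(cfg$chrom_lengths) >= 1 && !is.null(names(cfg$chrom_lengths)) &&
        all(nzchar(names(cfg$chrom_lengths))),
      "chrom_lengths must be a named vector")
  chk(all(cfg$chrom_lengths > 0), "chromosome lengths must be positive")
  chk(cfg$marker_density >= 0, "marker_density must be >= 0")
  chk(cfg$n_dh_lines >= 1, "n_dh_lines must be >= 1")
  chk(cfg$crossover_rate_lambda >= 0, "crossover_rate_lambda must be >= 0")
  for (p in c("genotype_error_eps", "missing_rate", "residual_het_rate")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, sprintf("%s must be in [0, 1]", p))
  }
  chk(cfg$genotype_error_eps + cfg$missing_rate <= 1,
      "genotype_error_eps + missing_rate must be <= 1")
  if (!is.null(cfg$causal_region)) {
    cr <- cfg$causal_region
    if (!all(c("chrom", "start", "end", "high_label") %in% names(cr))) {
      errs <- c(errs, "causal_region needs chrom, start, end, high_label")
    } else {
      chk(cr$chrom %in% names(cfg$chrom_lengths),
          "causal_region chromosome not in chrom_lengths")
      if (cr$chrom %in% names(cfg$chrom_lengths))
        chk(cr$start >= 1 && cr$end <= cfg$chrom_lengths[[cr$chrom]] &&
              cr$start <= cr$end,
            "causal_region must lie inside its chromosome")
      chk(cr$high_label %in% c("P1", "P2"),
          "causal_region high_label must be P1 or P2")
    }
  }
  pp <- cfg$phenotype_params
  chk(all(c("mean_high", "sd_high", "mean_low", "sd_low") %in% names(pp)),
      "phenotype_params needs mean_high, sd_high, mean_low, sd_low")
  chk(abs(sum(cfg$compound_fractions) - 1) < 1e-8,
      "compound_fractions must sum to 1")
  errs
}

dh_line_names <- function(n) sprintf("DH%03d", seq_len(n))

#' Simulate parent-informative markers
#'
#' Draws marker positions uniformly along each chromosome at the configured
#' density (count Poisson-distributed), assigns each a biallelic SNP or small
#' InDel with the two parents homozygous for different alleles.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `p1_allele`,
#'   `p2_allele`, `class` ("SNP"/"InDel"), sorted by (chrom, pos), unique
#'   positions per chromosome.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "dh_sim_config"))
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(config$chrom_lengths), function(chr) {
    len <- config$chrom_lengths[[chr]]
    with_seed(derive_seed(config$seed, "markers", chr), {
      n <- stats::rpois(1, len * config$marker_density)
      n <- min(n, len)
      if (n == 0) return(NULL)
      pos <- sort(sample.int(len, n))
      ref <- sample(bases, n, replace = TRUE)
      is_indel <- stats::runif(n) < 0.1
      alt <- character(n)
      for (i in seq_len(n)) {
        alt[i] <- if (is_indel[i]) {
          paste0(ref[i], paste(sample(bases, sample(1:3, 1), replace = TRUE),
                               collapse = ""))
        } else sample(setdiff(bases, ref[i]), 1)
      }
      p1_is_ref <- stats::runif(n) < 0.5
      data.frame(chrom = chr, pos = pos, ref = ref, alt = alt,
                 p1_allele = ifelse(p1_is_ref, ref, alt),
                 p2_allele = ifelse(p1_is_ref, alt, ref),
                 class = ifelse(is_indel, "InDel", "SNP"),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), p1_allele = character(),
                      p2_allele = character(), class = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate DH recombinant mosaics (ground truth)
#'
#' Per line and chromosome, draws a Poisson number of crossovers placed
#' uniformly in physical coordinates (no interference), starts from P1 or P2
#' with probability 1/2, alternates labels at each crossover, and optionally
#' relabels whole segments HET at the residual heterozygosity rate.
#'
#' @param config a [sim_config()] object.
#' @param markers marker table from [simulate_markers()] (carried along for
#'   downstream convenience; the mosaic itself is marker-free).
#' @return list of class `dh_truth` with elements `segments` (data.frame
#'   line/chrom/start/end/label tiling each chromosome), `crossovers`
#'   (data.frame line/chrom/pos) and `lines` (character vector).
#' @export
simulate_dh_mosaics <- function(config, markers = NULL) {
  stopifnot(inherits(config, "dh_sim_config"))
  lines <- dh_line_names(config$n_dh_lines)
  seg_list <- list()
  xo_list <- list()
  for (ln in lines) {
    for (chr in names(config$chrom_lengths)) {
      len <- config$chrom_lengths[[chr]]
      res <- with_seed(derive_seed(config$seed, "mosaic", ln, chr), {
        k <- stats::rpois(1, config$crossover_rate_lambda)
        xo <- sort(stats::runif(k, min = 1, max = len))
        start_label <- sample(c("P1", "P2"), 1)
        bounds <- c(1, floor(xo) + 1, len + 1)
        nseg <- length(bounds) - 1
        labels <- rep(c(start_label, setdiff(c("P1", "P2"), start_label)),
                      length.out = nseg)
        if (config$residual_het_rate > 0) {
          to_het <- stats::runif(nseg) < config$residual_het_rate
          labels[to_het] <- "HET"
        }
        list(xo = floor(xo), bounds = bounds, labels = labels)
      })
      segs <- data.frame(line = ln, chrom = chr,
                         start = res$bounds[-length(res$bounds)],
                         end = res$bounds[-1] - 1,
                         label = res$labels, stringsAsFactors = FALSE)
      # residual-het relabelling can create equal adjacent labels; coalesce
      segs <- coalesce_segments(segs)
      seg_list[[length(seg_list) + 1]] <- segs
      if (length(res$xo)) {
        xo_list[[length(xo_list) + 1]] <-
          data.frame(line = ln, chrom = chr, pos = res$xo,
                     stringsAsFactors = FALSE)
      }
    }
  }
  segments <- do.call(rbind, seg_list)
  crossovers <- if (length(xo_list)) do.call(rbind, xo_list) else
    data.frame(line = character(), chrom = character(), pos = integer())
  rownames(segments) <- NULL
  structure(list(segments = segments, crossovers = crossovers, lines = lines),
            class = "dh_truth")
}

coalesce_segments <- function(segs) {
  if (nrow(segs) <= 1) return(segs)
  keep <- c(TRUE, segs$label[-1] != segs$label[-nrow(segs)])
  grp <- cumsum(keep)
  out <- segs[keep, , drop = FALSE]
  out$end <- tapply(segs$end, grp, max)
  rownames(out) <- NULL
  out
}

# True origin label of one line at given positions on one chromosome.
truth_label_at <- function(truth, line, chrom, positions) {
  segs <- truth$segments[truth$segments$line == line &
                           truth$segments$chrom == chrom, , drop = FALSE]
  if (!nrow(segs)) return(rep(NA_character_, length(positions)))
  idx <- findInterval(positions, segs$start)
  idx[idx < 1] <- NA
  segs$label[idx]
}

#' Observe noisy genotype calls and (optionally) write a VCF
#'
#' Applies the observation model to the true mosaics at each marker: the call
#' equals the truth with probability `1 - eps - missing_rate`, is a uniformly
#' chosen wrong label with probability `eps`, and MISSING with probability
#' `missing_rate`.  Optionally encodes parents and DH lines as a multi-sample
#' VCF v4.2 (GT-only).
#'
#' @param truth a `dh_truth` object.
#' @param markers marker table from [simulate_markers()].
#' @param config the generating [sim_config()].
#' @param vcf_path if non-NULL, write a VCF there.
#' @param p1_name,p2_name parent sample names used in the VCF header.
#' @return list with `calls` (character matrix markers x lines of origin
#'   labels), `markers`, and `vcf_path` (NULL if not written).
#' @export
observe_genotypes <- function(truth, markers, config, vcf_path = NULL,
                              p1_name = "P1", p2_name = "P2") {
  stopifnot(inherits(truth, "dh_truth"), inherits(config, "dh_sim_config"))
  lines <- truth$lines
  nm <- nrow(markers)
  calls <- matrix(NA_character_, nrow = nm, ncol = length(lines),
                  dimnames = list(NULL, lines))
  eps <- config$genotype_error_eps
  miss <- config$missing_rate
  for (ln in lines) {
    true_lab <- character(nm)
    for (chr in unique(markers$chrom)) {
      sel <- markers$chrom == chr
      true_lab[sel] <- truth_label_at(truth, ln, chr, markers$pos[sel])
    }
    obs <- with_seed(derive_seed(config$seed, "observe", ln), {
      u <- stats::runif(nm)
      out <- true_lab
      out[u < eps + miss] <- "MISSING"
      err <- which(u < eps)
      if (length(err)) {
        out[err] <- vapply(true_lab[err], function(tl)
          sample(setdiff(STATE_LABELS, tl), 1), character(1))
      }
      out
    })
    calls[, ln] <- obs
  }
  if (!is.null(vcf_path)) {
    write_sim_vcf(vcf_path, markers, calls, p1_name, p2_name)
  }
  list(calls = calls, markers = markers, vcf_path = vcf_path)
}

# Encode origin labels as VCF genotypes.  Parents are homozygous for their
# own alleles; DH calls translate P1/P2/HET/MISSING through the parental
# allele indices at each marker.
write_sim_vcf <- function(path, markers, calls, p1_name, p2_name) {
  p1_idx <- ifelse(markers$p1_allele == markers$ref, 0L, 1L)
  p2_idx <- 1L - p1_idx
  gt_of <- function(i) paste0(i, "/", i)
  enc <- function(lab, i) {
    out <- rep("./.", length(lab))
    out[lab == "P1"] <- gt_of(p1_idx[i][lab == "P1"])
    out[lab == "P2"] <- gt_of(p2_idx[i][lab == "P2"])
    out[lab == "HET"] <- "0/1"
    out
  }
  idx <- seq_len(nrow(markers))
  cols <- c(list(markers$chrom, markers$pos, ".", markers$ref, markers$alt,
                 "60", "PASS", ".", "GT",
                 gt_of(p1_idx), gt_of(p2_idx)),
            lapply(colnames(calls), function(ln) enc(calls[, ln], idx)))
  body <- do.call(paste, c(cols, sep = "\t"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dhblocks-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=", unique(markers$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", p1_name, p2_name, colnames(calls)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate metabolite phenotypes linked to the causal region
#'
#' A line whose true origin at the causal-region midpoint equals the
#' configured high-origin label draws its total from the high regime
#' Normal(mean_high, sd_high); otherwise (including HET, and lines where no
#' segment covers the midpoint, which are flagged) from the low regime.  The
#' total of each replicate is split into component compounds by the
#' configured fixed fractions.
#'
#' @param truth a `dh_truth` object.
#' @param config the generating [sim_config()]; must carry a causal_region.
#' @return data.frame with columns `line`, `replicate`, `compound`, `value`;
#'   attribute `groups` is a data.frame (line, group in "high"/"low",
#'   flagged) giving the true phenotype group.
#' @export
simulate_metabolites <- function(truth, config) {
  stopifnot(inherits(truth, "dh_truth"), inherits(config, "dh_sim_config"))
  cr <- config$causal_region
  if (is.null(cr)) stopf("config has no causal_region")
  pp <- config$phenotype_params
  mid <- floor((cr$start + cr$end) / 2)
  frac <- config$compound_fractions
  rows <- list()
  groups <- list()
  for (ln in truth$lines) {
    lab <- truth_label_at(truth, ln, cr$chrom, mid)
    flagged <- is.na(lab)
    high <- !flagged && identical(lab, cr$high_label)
    mu <- if (high) pp$mean_high else pp$mean_low
    sdv <- if (high) pp$sd_high else pp$sd_low
    totals <- with_seed(derive_seed(config$seed, "pheno", ln),
                        stats::rnorm(config$n_replicates, mu, sdv))
    totals <- pmax(totals, 0)
    rows[[ln]] <- data.frame(
      line = ln,
      replicate = rep(seq_len(config$n_replicates), each = length(frac)),
      compound = rep(names(frac), times = config$n_replicates),
      value = as.vector(vapply(totals, function(t) t * frac,
                               numeric(length(frac)))),
      stringsAsFactors = FALSE)
    groups[[ln]] <- data.frame(line = ln,
                               group = if (high) "high" else "low",
                               flagged = flagged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "groups") <- do.call(rbind, c(groups, list(make.row.names = FALSE)))
  out
}

#' Simulate a full DH population with files on disk
#'
#' Convenience wrapper chaining [simulate_markers()], [simulate_dh_mosaics()],
#' [observe_genotypes()] and (when a causal region is configured)
#' [simulate_metabolites()].  When `out_dir` is given, writes `sim.vcf`,
#' `truth.bed` (0-based half-open), and `phenotypes.csv`.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional output directory.
#' @param p1_name,p2_name parent sample names for the VCF.
#' @return list with `markers`, `truth`, `calls`, `phenotypes` (or NULL),
#'   `paths` (named list of files written, possibly empty).
#' @export
simulate_population <- function(config, out_dir = NULL,
                                p1_name = "P1", p2_name = "P2") {
  markers <- simulate_markers(config)
  truth <- simulate_dh_mosaics(config, markers)
  paths <- list()
  vcf_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vcf_path <- file.path(out_dir, "sim.vcf")
  }
  obs <- observe_genotypes(truth, markers, config, vcf_path = vcf_path,
                           p1_name = p1_name, p2_name = p2_name)
  pheno <- NULL
  if (!is.null(config$causal_region)) pheno <- simulate_metabolites(truth, config)
  if (!is.null(out_dir)) {
    paths$vcf <- vcf_path
    bed <- truth$segments
    bed_df <- data.frame(chrom = bed$chrom, start = bed$start - 1L,
                         end = bed$end, line = bed$line, label = bed$label)
    paths$truth_bed <- file.path(out_dir, "truth.bed")
    utils::write.table(bed_df, paths$truth_bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(pheno)) {
      paths$phenotypes <- file.path(out_dir, "phenotypes.csv")
      utils::write.csv(pheno, paths$phenotypes, row.names = FALSE)
    }
  }
  list(markers = markers, truth = truth, calls = obs$calls,
       phenotypes = pheno, paths = paths)
}
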
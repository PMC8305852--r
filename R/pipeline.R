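#' Validate a pipeline configuration
#'
#' Checks a pipeline config (a nested list, typically read from YAML via
#' [read_pipeline_config()]) and returns every problem found, collected
#' together rather than failing at the first.
#'
#' @param config nested list; see [run_pipeline()] for the expected shape.
#' @return character vector of error messages; empty when valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)
  has_sim <- !is.null(config$simulation)
  has_vcf <- !is.null(config$inputs$vcf)
  if (!has_sim && !has_vcf && is.null(config$inputs$metabolites) &&
      is.null(config$inputs$genes))
    add("either a simulation section or input paths must be present")
  if (has_sim) {
    sim <- config$simulation
    cl <- sim$chrom_lengths
    if (is.null(cl)) {
      add("simulation.chrom_lengths missing")
    } else {
      cfg_try <- tryCatch(
        validate_sim_config(structure(
          utils::modifyList(formals_defaults_sim(), sim, keep.null = TRUE),
          class = "dh_sim_config")),
        error = function(e) conditionMessage(e))
      if (is.character(cfg_try)) errs <- c(errs, cfg_try)
    }
  }
  for (f in c("vcf", "genes", "metabolites", "groups")) {
    p <- config$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      add(sprintf("input file not found (%s): %s", f, p))
  }
  if (has_vcf && (is.null(config$parents$p1) || is.null(config$parents$p2)))
    add("parents.p1 and parents.p2 are required with a VCF input")
  hp <- config$hmm
  if (!is.null(hp)) {
    chk <- tryCatch({
      do.call(hmm_params, hp)
      NULL
    }, error = function(e) sprintf("invalid hmm parameters: %s",
                                   conditionMessage(e)))
    if (!is.null(chk)) add(chk)
  }
  if (!is.null(config$stats$alpha) &&
      (config$stats$alpha <= 0 || config$stats$alpha >= 1))
    add("stats.alpha must be in (0, 1)")
  errs
}

formals_defaults_sim <- function() {
  f <- formals(sim_config)
  f <- f[setdiff(names(f), "chrom_lengths")]
  lapply(f, function(x) if (is.language(x)) eval(x) else x)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file.
#' @return nested config list with `simulation$chrom_lengths` coerced to a
#'   named numeric vector.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulation$chrom_lengths))
    cfg$simulation$chrom_lengths <- unlist(cfg$simulation$chrom_lengths)
  cfg
}

#' Run the whole inference chain
#'
#' Orchestrates simulate (optional) -> marker extraction -> origin calls ->
#' block calling -> gene matrix / co-segregation (when annotations and
#' groups are given) -> metabolite statistics, writing every stage product
#' to `out_dir` as plain-text files plus a JSON run manifest and a summary
#' report.  Identical config and seed give byte-identical outputs.
#'
#' Config shape (all sections optional unless noted):
#' \describe{
#'   \item{simulation}{arguments of [sim_config()] minus `seed`.}
#'   \item{inputs}{`vcf`, `genes`, `metabolites` (summary CSV), `groups`
#'     (CSV line,group with groups "A"/"B" or "high"/"low").}
#'   \item{parents}{`p1`, `p2` sample names (required with a VCF).}
#'   \item{hmm}{arguments of [hmm_params()].}
#'   \item{coseg}{`min_markers`, `max_violations`.}
#'   \item{stats}{`alpha`, `method`.}
#' }
#'
#' @param config nested list (see above).
#' @param out_dir output directory.
#' @param seed integer seed for all randomness.
#' @return invisible list with the in-memory stage products (`markers`,
#'   `blocks`, `regions`, `coseg_genes`, `gene_matrix`, `metabolites`,
#'   `paths`).
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  errs <- validate_config(config)
  if (length(errs))
    stopf("invalid pipeline config:\n- %s", paste(errs, collapse = "\n- "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage %s: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    message(sprintf("[%s] %s (%.2fs)", format(Sys.time(), "%H:%M:%S"), name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  paths <- list()
  results <- list()
  p1 <- config$parents$p1 %||% "P1"
  p2 <- config$parents$p2 %||% "P2"
  vcf_path <- config$inputs$vcf
  groups <- NULL

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", {
      args <- config$simulation
      args$seed <- seed
      cfg <- do.call(sim_config, args)
      simulate_population(cfg, out_dir = out_dir, p1_name = p1, p2_name = p2)
    })
    vcf_path <- sim$paths$vcf
    results$truth <- sim$truth
    if (!is.null(sim$phenotypes)) {
      g <- attr(sim$phenotypes, "groups")
      groups <- data.frame(line = g$line,
                           group = ifelse(g$group == "high", "A", "B"),
                           stringsAsFactors = FALSE)
      paths$groups <- file.path(out_dir, "groups.csv")
      utils::write.csv(groups, paths$groups, row.names = FALSE)
    }
  }

  if (!is.null(vcf_path)) {
    records <- stage("read_vcf", read_vcf(vcf_path, c(p1, p2)))
    markers <- stage("markers", {
      m <- extract_informative_markers(
        records, p1, p2,
        min_qual = config$filters$min_qual %||% 20,
        snp_only = isTRUE(config$filters$snp_only))
      paths$markers <- file.path(out_dir, "markers.tsv")
      write_markers_tsv(m, paths$markers)
      m
    })
    results$markers <- markers
    line_names <- setdiff(names(records),
                          c("chrom", "pos", "ref", "alt", "qual", p1, p2))
    calls <- stage("origin_calls",
                   call_origins_matrix(markers, records, line_names))
    params <- do.call(hmm_params, config$hmm %||% list())
    blocks <- stage("blocks", {
      b <- call_blocks_all(calls, markers, params)
      paths$blocks_tsv <- file.path(out_dir, "blocks.tsv")
      paths$blocks_bed <- file.path(out_dir, "blocks.bed")
      write_blocks(b, paths$blocks_tsv, paths$blocks_bed)
      paths$painting <- file.path(out_dir, "painting.csv")
      pm <- paint_chromosomes(calls, markers, params)
      utils::write.csv(cbind(markers[c("chrom", "pos")], pm),
                       paths$painting, row.names = FALSE)
      b
    })
    results$blocks <- blocks

    if (is.null(groups) && !is.null(config$inputs$groups)) {
      groups <- utils::read.csv(config$inputs$groups,
                                stringsAsFactors = FALSE)
    }
    if (!is.null(groups)) {
      groupA <- groups$line[groups$group %in% c("A", "high")]
      groupB <- groups$line[groups$group %in% c("B", "low")]
      if (length(groupA) && length(groupB)) {
        results$regions <- stage("coseg_regions", {
          r <- find_cosegregating_regions(
            markers, blocks, groupA, groupB,
            min_markers = config$coseg$min_markers %||% 10)
          paths$regions <- file.path(out_dir, "coseg_regions.tsv")
          utils::write.table(r, paths$regions, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          r
        })
      }
    }
    if (!is.null(config$inputs$genes)) {
      genes <- read_gene_table(config$inputs$genes)
      results$gene_matrix <- stage("gene_matrix", {
        gm <- build_gene_matrix(blocks, genes, lines = colnames(calls))
        paths$gene_matrix <- file.path(out_dir, "gene_matrix.csv")
        if (!is.null(groups)) {
          write_gene_matrix(gm, paths$gene_matrix,
                            groupA = groups$line[groups$group %in% c("A", "high")],
                            groupB = groups$line[groups$group %in% c("B", "low")])
        } else write_gene_matrix(gm, paths$gene_matrix)
        gm
      })
      if (!is.null(groups)) {
        results$coseg_genes <- find_cosegregating_genes(
          results$gene_matrix,
          groups$line[groups$group %in% c("A", "high")],
          groups$line[groups$group %in% c("B", "low")],
          max_violations = config$coseg$max_violations %||% 0)
      }
    }
  }

  if (!is.null(config$inputs$metabolites)) {
    results$metabolites <- stage("metabolites", {
      tab <- read_metabolite_summary(config$inputs$metabolites)
      lines <- unique(tab$line)
      rep <- data.frame(line = lines,
                        total = vapply(lines, function(ln)
                          total_concentration(tab, ln), numeric(1)))
      paths$metabolite_report <- file.path(out_dir, "metabolite_totals.csv")
      utils::write.csv(rep, paths$metabolite_report, row.names = FALSE)
      list(table = tab, totals = rep)
    })
  }

  summary_lines <- c(
    sprintf("dhblocks run, seed %d", as.integer(seed)),
    if (!is.null(results$markers))
      sprintf("informative markers: %d", nrow(results$markers)),
    if (!is.null(results$blocks)) c(
      sprintf("blocks (per-line total): %d", nrow(results$blocks)),
      sprintf("blocks (union intervals): %d",
              count_union_blocks(results$blocks))),
    if (!is.null(results$regions))
      sprintf("co-segregating regions: %d (markers: %s)",
              nrow(results$regions),
              paste(results$regions$n_markers, collapse = ",")),
    if (!is.null(results$coseg_genes))
      sprintf("co-segregating genes: %d", nrow(results$coseg_genes)))
  paths$summary <- file.path(out_dir, "summary.txt")
  writeLines(summary_lines, paths$summary)

  manifest <- list(
    package = "dhblocks",
    version = as.character(utils::packageVersion("dhblocks")),
    seed = as.integer(seed),
    config_hash = config_hash(config),
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  results$paths <- paths
  invisible(results)
}

# Order-independent hash of the config list (no external digest dependency).
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
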
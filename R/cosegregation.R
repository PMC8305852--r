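#' Read a gene annotation table
#'
#' Expects a TSV/CSV with at least `chrom`, `start`, `stop`, `name` and
#' optionally `gene_id_v1_5`, `gene_id_v3_0`, `stage` columns (the layout of
#' a pathway-annotated gene list; 1-based inclusive coordinates).
#'
#' @param path annotation file; delimiter inferred from the extension.
#' @return data.frame of gene models.
#' @export
read_gene_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  g <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, quote = "\"",
                         check.names = FALSE)
  need <- c("chrom", "start", "stop", "name")
  missing_c <- setdiff(need, names(g))
  if (length(missing_c))
    stopf("gene table lacks column(s): %s", paste(missing_c, collapse = ", "))
  stopifnot(all(g$start <= g$stop))
  g
}

#' Assign a gene's parental origin from one line's blocks
#'
#' The gene takes the label of the block containing its midpoint
#' `floor((start + stop) / 2)`.  A midpoint falling in an unlabeled gap
#' between blocks yields NA.  If the gene interval additionally overlaps a
#' block of a different label, the assignment is flagged boundary-spanning.
#'
#' @param blocks block table for one line and (at least) the gene's
#'   chromosome.
#' @param gene one-row data.frame (or list) with `chrom`, `start`, `stop`.
#' @return list with `label` (character or NA) and `boundary` (logical).
#' @export
assign_gene_origin <- function(blocks, gene) {
  b <- blocks[blocks$chrom == gene$chrom, , drop = FALSE]
  mid <- floor((gene$start + gene$stop) / 2)
  hit <- which(b$start <= mid & b$end >= mid)
  if (!length(hit)) return(list(label = NA_character_, boundary = FALSE))
  lab <- b$label[hit[1]]
  overlap <- b$start <= gene$stop & b$end >= gene$start
  boundary <- any(b$label[overlap] != lab)
  list(label = lab, boundary = boundary)
}

#' Build a gene-by-line parental-origin matrix
#'
#' One row per gene, one column per line; each cell is the line's origin
#' label at that gene per [assign_gene_origin()].  Parent columns, when
#' requested, are filled with their own labels.  Row order preserves the
#' input gene order.
#'
#' @param blocks block table for all lines.
#' @param genes gene table (see [read_gene_table()]).
#' @param lines line names (default: lines present in `blocks`).
#' @param p1_name,p2_name optional parent column names to prepend/append.
#' @return list of class `dh_gene_matrix` with `genes` (data.frame),
#'   `labels` (character matrix genes x lines) and `boundary` (logical
#'   matrix).
#' @export
build_gene_matrix <- function(blocks, genes, lines = NULL,
                              p1_name = NULL, p2_name = NULL) {
  if (is.null(lines)) lines <- unique(blocks$line)
  ng <- nrow(genes)
  all_cols <- c(p1_name, lines, p2_name)
  labels <- matrix(NA_character_, nrow = ng, ncol = length(all_cols),
                   dimnames = list(NULL, all_cols))
  boundary <- matrix(FALSE, nrow = ng, ncol = length(all_cols),
                     dimnames = list(NULL, all_cols))
  block_chroms <- unique(blocks$chrom)
  for (ln in lines) {
    lb <- blocks[blocks$line == ln, , drop = FALSE]
    for (i in seq_len(ng)) {
      if (!genes$chrom[i] %in% block_chroms) next
      a <- assign_gene_origin(lb, genes[i, ])
      labels[i, ln] <- a$label
      boundary[i, ln] <- a$boundary
    }
  }
  absent <- setdiff(unique(genes$chrom), block_chroms)
  if (length(absent))
    warnf("gene chromosome(s) absent from block set: %s",
          paste(absent, collapse = ", "))
  if (!is.null(p1_name)) labels[, p1_name] <- "P1"
  if (!is.null(p2_name)) labels[, p2_name] <- "P2"
  structure(list(genes = genes, labels = labels, boundary = boundary),
            class = "dh_gene_matrix")
}

#' Genes whose parental origin perfectly separates two phenotype groups
#'
#' A gene qualifies when every group-A cell carries one definite parental
#' label, every group-B cell carries the other, and no cell in either group
#' is HET or NA.  Either orientation qualifies and is reported.  Perfect
#' separation is the normative filter; `max_violations` relaxes it by
#' allowing up to that many disagreeing cells per gene (default 0).
#'
#' @param matrix a `dh_gene_matrix` (or a plain character matrix with gene
#'   rows and line columns).
#' @param groupA,groupB disjoint, non-empty sets of line (column) names.
#' @param max_violations allowed number of non-conforming cells (default 0).
#' @param parent_labels the two parental labels used in the matrix cells
#'   (default `c("P1", "P2")`; e.g. `c("LP08", "LP21")` for a matrix typed by
#'   parent accession names).
#' @return data.frame of qualifying genes with `groupA_label`,
#'   `groupB_label` columns appended; zero rows if none qualify.
#' @export
find_cosegregating_genes <- function(matrix, groupA, groupB,
                                     max_violations = 0,
                                     parent_labels = c("P1", "P2")) {
  lab <- if (inherits(matrix, "dh_gene_matrix")) matrix$labels else matrix
  genes <- if (inherits(matrix, "dh_gene_matrix")) matrix$genes else
    data.frame(row = seq_len(nrow(lab)))
  if (!length(groupA) || !length(groupB)) stopf("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stopf("groups overlap")
  missing_l <- setdiff(c(groupA, groupB), colnames(lab))
  if (length(missing_l))
    stopf("line(s) not in matrix: %s", paste(missing_l, collapse = ", "))
  ok <- logical(nrow(lab))
  labA <- labB <- rep(NA_character_, nrow(lab))
  for (i in seq_len(nrow(lab))) {
    a <- lab[i, groupA]
    b <- lab[i, groupB]
    for (ori in list(parent_labels, rev(parent_labels))) {
      viol <- sum(is.na(a) | a != ori[1]) + sum(is.na(b) | b != ori[2])
      if (viol <= max_violations) {
        ok[i] <- TRUE
        labA[i] <- ori[1]
        labB[i] <- ori[2]
        break
      }
    }
  }
  out <- genes[ok, , drop = FALSE]
  out$groupA_label <- labA[ok]
  out$groupB_label <- labB[ok]
  rownames(out) <- NULL
  out
}

#' Marker regions whose parental origin perfectly separates two groups
#'
#' Scans each chromosome's informative markers using per-marker labels
#' derived from the block calls: a maximal run of consecutive markers at
#' which every group-A line shares one parental label and every group-B line
#' shares the other becomes a region bounded by its first and last marker.
#' Runs shorter than `min_markers` are suppressed.
#'
#' @param markers marker table (columns `chrom`, `pos`).
#' @param blocks block table for all lines.
#' @param groupA,groupB disjoint, non-empty line sets.
#' @param min_markers minimum run length to report (default 10).
#' @param parent_labels the two parental labels (default `c("P1", "P2")`).
#' @return data.frame of regions: `chrom`, `start`, `end`, `n_markers`,
#'   `groupA_label`, `groupB_label`.
#' @export
find_cosegregating_regions <- function(markers, blocks, groupA, groupB,
                                       min_markers = 10,
                                       parent_labels = c("P1", "P2")) {
  if (!length(groupA) || !length(groupB)) stopf("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stopf("groups overlap")
  lines <- c(groupA, groupB)
  regions <- list()
  for (chr in unique(markers$chrom)) {
    pos <- markers$pos[markers$chrom == chr]
    if (!length(pos)) next
    lab <- matrix(NA_character_, nrow = length(pos), ncol = length(lines),
                  dimnames = list(NULL, lines))
    for (ln in lines) {
      lb <- blocks[blocks$line == ln & blocks$chrom == chr, , drop = FALSE]
      if (!nrow(lb)) next
      idx <- findInterval(pos, lb$start)
      in_block <- idx >= 1 & pos <= lb$end[pmax(idx, 1)]
      lab[in_block, ln] <- lb$label[idx[in_block]]
    }
    a <- lab[, groupA, drop = FALSE]
    b <- lab[, groupB, drop = FALSE]
    sep_with <- function(x, y) {
      rowSums(a == x, na.rm = TRUE) == length(groupA) &
        rowSums(is.na(a)) == 0 &
        rowSums(b == y, na.rm = TRUE) == length(groupB) &
        rowSums(is.na(b)) == 0
    }
    for (ori in list(parent_labels, rev(parent_labels))) {
      sep <- sep_with(ori[1], ori[2])
      r <- rle(sep)
      ends <- cumsum(r$lengths)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      for (j in which(r$values & r$lengths >= min_markers)) {
        regions[[length(regions) + 1]] <- data.frame(
          chrom = chr, start = pos[starts[j]], end = pos[ends[j]],
          n_markers = r$lengths[j],
          groupA_label = ori[1], groupB_label = ori[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(regions)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_markers = integer(), groupA_label = character(),
                      groupB_label = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pathway-stage genotype profile of one line
#'
#' Groups the line's gene labels by pathway stage and reports, per stage and
#' label, the count and the gene names — the per-line stepwise pathway
#' comparison view.
#'
#' @param matrix a `dh_gene_matrix` whose gene table has a `stage` column.
#' @param line a line (column) name.
#' @return data.frame with `stage`, `label`, `n`, `genes` (comma-separated).
#' @export
pathway_profile <- function(matrix, line) {
  stopifnot(inherits(matrix, "dh_gene_matrix"))
  if (!line %in% colnames(matrix$labels)) stopf("unknown line: %s", line)
  if (!"stage" %in% names(matrix$genes)) stopf("gene table has no stage column")
  lab <- matrix$labels[, line]
  lab[is.na(lab)] <- "NA"
  df <- data.frame(stage = matrix$genes$stage, name = matrix$genes$name,
                   label = lab, stringsAsFactors = FALSE)
  agg <- stats::aggregate(name ~ stage + label, data = df, FUN = function(x)
    paste(x, collapse = ","))
  agg$n <- vapply(strsplit(agg$name, ","), length, integer(1))
  out <- agg[order(agg$stage, agg$label), c("stage", "label", "n", "name")]
  names(out)[4] <- "genes"
  rownames(out) <- NULL
  out
}

#' Write the gene matrix as CSV
#'
#' Genes as rows, lines as columns, plus a `coseg` boolean column marking the
#' perfectly co-segregating genes for the given grouping (omitted when no
#' groups are supplied).
#'
#' @param matrix a `dh_gene_matrix`.
#' @param path output CSV.
#' @param groupA,groupB optional line groups for the `coseg` column.
#' @export
write_gene_matrix <- function(matrix, path, groupA = NULL, groupB = NULL) {
  df <- cbind(matrix$genes, as.data.frame(matrix$labels,
                                          stringsAsFactors = FALSE))
  if (!is.null(groupA) && !is.null(groupB)) {
    cs <- find_cosegregating_genes(matrix, groupA, groupB)
    key <- paste(matrix$genes$chrom, matrix$genes$start, matrix$genes$stop)
    df$coseg <- key %in% paste(cs$chrom, cs$start, cs$stop)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
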
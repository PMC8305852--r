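#' HMM parameters for parental-origin block calling
#'
#' @param eps emission error probability: a marker's raw call matches the
#'   underlying state with probability `1 - eps`, each wrong label with
#'   probability `eps / 2` (default 0.02).
#' @param rho recombination rate in cM per Mb used to convert physical
#'   distance into recombination fraction via the Haldane map function
#'   (default 3.5, approximating a ~1000 cM map over a ~283 Mb genome; a
#'   tuning default, not an estimate).
#' @param het_prior stationary weight of the residual-heterozygosity state
#'   (default 0.01).
#' @param min_block_markers blocks supported by fewer markers are merged into
#'   a flanking block (default 5).
#' @return object of class `dh_hmm_params`.
#' @export
hmm_params <- function(eps = 0.02, rho = 3.5, het_prior = 0.01,
                       min_block_markers = 5) {
  stopifnot(eps > 0, eps < 0.5, rho > 0, het_prior >= 0, het_prior < 1,
            min_block_markers >= 1)
  structure(list(eps = eps, rho = rho, het_prior = het_prior,
                 min_block_markers = min_block_markers),
            class = "dh_hmm_params")
}

#' Distance-dependent state-transition matrix
#'
#' Converts the physical gap between consecutive markers into a genetic
#' distance `d = distance_bp * rho * 1e-8` Morgans and a recombination
#' fraction `r = (1 - exp(-2 d)) / 2` (Haldane).  Between the two parental
#' states the switch probability is `r`, split `(1 - het_prior)` to the other
#' parent and `het_prior` into HET; HET is left symmetrically.
#'
#' @param distance_bp non-negative physical distance in bp.
#' @param params [hmm_params()] object.
#' @return 3x3 row-stochastic matrix over states P1, P2, HET.
#' @export
transition_matrix <- function(distance_bp, params) {
  stopifnot(distance_bp >= 0)
  d <- distance_bp * params$rho * 1e-8
  r <- 0.5 * (1 - exp(-2 * d))
  h <- params$het_prior
  m <- matrix(c(1 - r, r * (1 - h), r * h,
                r * (1 - h), 1 - r, r * h,
                r / 2, r / 2, 1 - r),
              nrow = 3, byrow = TRUE,
              dimnames = list(STATE_LABELS, STATE_LABELS))
  # rows: P1 keeps 1-r + r*(1-h) + r*h = 1; HET row sums r/2+r/2+1-r = 1
  m["P1", "P1"] <- 1 - r * (1 - h) - r * h
  m["P2", "P2"] <- 1 - r * (1 - h) - r * h
  m
}

# Emission log-probabilities for one call under each state.  MISSING is
# emitted with probability 1 by every state (contributes nothing but keeps
# the marker's position in the distance chain).
emission_logprob <- function(call, eps) {
  if (call == "MISSING") return(c(P1 = 0, P2 = 0, HET = 0))
  lp <- rep(log(eps / 2), 3)
  names(lp) <- STATE_LABELS
  lp[call] <- log(1 - eps)
  lp
}

#' Viterbi decoding of a per-marker origin-call sequence
#'
#' Computes the maximum-a-posteriori state path over {P1, P2, HET} given the
#' raw origin calls, with emissions `1 - eps` (match) / `eps/2` (each wrong
#' label) / 1 (MISSING) and the distance-dependent transitions of
#' [transition_matrix()].  The initial distribution puts weight `het_prior`
#' on HET and splits the rest evenly between the parents.  Ties are broken by
#' remaining in the previous state; at the first marker, by preferring P1
#' over P2 over HET.
#'
#' @param calls character vector of labels in P1/P2/HET/MISSING.
#' @param positions strictly increasing bp positions, same length as calls.
#' @param params [hmm_params()] object.
#' @return list with `path` (character state sequence) and `log_prob` (joint
#'   log-probability of the returned path).
#' @export
viterbi_path <- function(calls, positions, params) {
  n <- length(calls)
  stopifnot(length(positions) == n)
  if (n == 0) return(list(path = character(), log_prob = 0))
  if (n > 1) stopifnot(all(diff(positions) > 0))
  h <- params$het_prior
  init <- log(c(P1 = (1 - h) / 2, P2 = (1 - h) / 2, HET = max(h, 1e-300)))
  delta <- matrix(-Inf, nrow = n, ncol = 3, dimnames = list(NULL, STATE_LABELS))
  back <- matrix(1L, nrow = n, ncol = 3)
  delta[1, ] <- init + emission_logprob(calls[1], params$eps)
  if (n > 1) {
    for (t in 2:n) {
      lt <- log(transition_matrix(positions[t] - positions[t - 1], params))
      e <- emission_logprob(calls[t], params$eps)
      for (s in 1:3) {
        cand <- delta[t - 1, ] + lt[, s]
        best <- max(cand)
        # tie-break: prefer staying (previous state == current state),
        # then P1 > P2 > HET order
        tied <- which(cand >= best - 1e-12)
        j <- if (s %in% tied) s else tied[1]
        back[t, s] <- j
        delta[t, s] <- cand[j] + e[s]
      }
    }
  }
  path_idx <- integer(n)
  fin <- delta[n, ]
  tied <- which(fin >= max(fin) - 1e-12)
  path_idx[n] <- tied[1]
  if (n > 1) for (t in (n - 1):1) path_idx[t] <- back[t + 1, path_idx[t + 1]]
  list(path = STATE_LABELS[path_idx], log_prob = max(fin))
}

#' Collapse a state path into recombinant blocks
#'
#' Maximal constant-label runs of the path become blocks whose start/end are
#' the positions of their first and last marker.  Blocks supported by fewer
#' than `min_block_markers` markers are then merged into the flanking block
#' with the greater marker support (left flank on ties), repeatedly until
#' stable; adjacent same-label blocks are coalesced and `n_discordant` is
#' recomputed against the raw calls.
#'
#' @param path state sequence from [viterbi_path()].
#' @param positions marker positions aligned with the path.
#' @param params [hmm_params()] object.
#' @param raw_calls raw origin calls used for `n_discordant`; defaults to the
#'   path itself.
#' @return data.frame of blocks: `start`, `end`, `label`, `n_markers`
#'   (non-MISSING supporting markers), `n_discordant`.
#' @export
path_to_blocks <- function(path, positions, params, raw_calls = path) {
  n <- length(path)
  if (n == 0) {
    return(data.frame(start = integer(), end = integer(), label = character(),
                      n_markers = integer(), n_discordant = integer()))
  }
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- data.frame(first = starts, last = ends, label = r$values,
                       stringsAsFactors = FALSE)
  support <- function(b) sum(raw_calls[b$first:b$last] != "MISSING")
  blocks$n_markers <- vapply(seq_len(nrow(blocks)), function(i)
    support(blocks[i, ]), integer(1))

  coalesce <- function(b) {
    while (nrow(b) > 1 && any(b$label[-1] == b$label[-nrow(b)])) {
      i <- which(b$label[-1] == b$label[-nrow(b)])[1]
      b$last[i] <- b$last[i + 1]
      b$n_markers[i] <- b$n_markers[i] + b$n_markers[i + 1]
      b <- b[-(i + 1), , drop = FALSE]
    }
    b
  }
  blocks <- coalesce(blocks)
  repeat {
    small <- which(blocks$n_markers < params$min_block_markers)
    if (!length(small) || nrow(blocks) == 1) break
    i <- small[1]
    left_n <- if (i > 1) blocks$n_markers[i - 1] else -Inf
    right_n <- if (i < nrow(blocks)) blocks$n_markers[i + 1] else -Inf
    into <- if (left_n >= right_n) i - 1L else i + 1L
    blocks$label[i] <- blocks$label[into]
    blocks <- coalesce(blocks)
  }
  out <- data.frame(
    start = positions[blocks$first],
    end = positions[blocks$last],
    label = blocks$label,
    n_markers = blocks$n_markers,
    n_discordant = vapply(seq_len(nrow(blocks)), function(i) {
      idx <- blocks$first[i]:blocks$last[i]
      sum(raw_calls[idx] != "MISSING" & raw_calls[idx] != blocks$label[i])
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call recombinant blocks for one line across chromosomes
#'
#' Wrapper composing [viterbi_path()] and [path_to_blocks()] independently
#' per chromosome.
#'
#' @param calls character vector of raw origin labels for one line.
#' @param markers marker table aligned with `calls` (columns `chrom`, `pos`).
#' @param params [hmm_params()] object.
#' @param line line name recorded in the output.
#' @return data.frame of blocks: `line`, `chrom`, `start`, `end`, `label`,
#'   `n_markers`, `n_discordant`.
#' @export
call_blocks <- function(calls, markers, params = hmm_params(), line = "line") {
  stopifnot(length(calls) == nrow(markers))
  out <- list()
  for (chr in unique(markers$chrom)) {
    sel <- which(markers$chrom == chr)
    if (!length(sel)) {
      warnf("chromosome %s has no markers; no blocks called", chr)
      next
    }
    vp <- viterbi_path(calls[sel], markers$pos[sel], params)
    b <- path_to_blocks(vp$path, markers$pos[sel], params,
                        raw_calls = calls[sel])
    if (nrow(b)) {
      b <- cbind(line = line, chrom = chr, b, stringsAsFactors = FALSE)
      out[[chr]] <- b
    }
  }
  if (!length(out)) {
    return(data.frame(line = character(), chrom = character(),
                      start = integer(), end = integer(), label = character(),
                      n_markers = integer(), n_discordant = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call blocks for every line of a call matrix
#'
#' @param call_matrix character matrix (markers x lines) of raw origin labels.
#' @param markers marker table aligned with the rows.
#' @param params [hmm_params()] object.
#' @return data.frame of blocks for all lines.
#' @export
call_blocks_all <- function(call_matrix, markers, params = hmm_params()) {
  res <- lapply(colnames(call_matrix), function(ln)
    call_blocks(call_matrix[, ln], markers, params, line = ln))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-marker decoded labels for every line
#'
#' The marker-by-line matrix of Viterbi states — the "graphical genotype"
#' (chromosome-painting) form of the block calls.
#'
#' @inheritParams call_blocks_all
#' @return character matrix (markers x lines) of decoded states.
#' @export
paint_chromosomes <- function(call_matrix, markers, params = hmm_params()) {
  out <- matrix(NA_character_, nrow = nrow(markers), ncol = ncol(call_matrix),
                dimnames = list(NULL, colnames(call_matrix)))
  for (ln in colnames(call_matrix)) {
    for (chr in unique(markers$chrom)) {
      sel <- which(markers$chrom == chr)
      vp <- viterbi_path(call_matrix[sel, ln], markers$pos[sel], params)
      out[sel, ln] <- decoded_with_merge(vp$path, markers$pos[sel], params,
                                         call_matrix[sel, ln])
    }
  }
  out
}

# Post-merge per-marker labels: expand the merged blocks back onto markers.
decoded_with_merge <- function(path, positions, params, raw_calls) {
  b <- path_to_blocks(path, positions, params, raw_calls)
  lab <- character(length(positions))
  for (i in seq_len(nrow(b))) {
    lab[positions >= b$start[i] & positions <= b$end[i]] <- b$label[i]
  }
  lab
}

#' Write blocks as TSV and BED
#'
#' TSV keeps 1-based inclusive coordinates; BED converts to 0-based
#' half-open at the boundary.
#'
#' @param blocks block table from [call_blocks_all()].
#' @param tsv_path,bed_path output files (either may be NULL).
#' @export
write_blocks <- function(blocks, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(blocks, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = blocks$chrom, start = blocks$start - 1L,
                      end = blocks$end, name = paste(blocks$line,
                                                     blocks$label, sep = "_"))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Union breakpoint-interval block count across a population
#'
#' Distinct (chromosome, start, end, label) combinations over all lines — a
#' population-level companion to the per-line block count, since a single
#' "number of blocks" can be counted either way.
#'
#' @param blocks block table.
#' @return integer count of distinct population-level block intervals.
#' @export
count_union_blocks <- function(blocks) {
  nrow(unique(blocks[c("chrom", "start", "end", "label")]))
}
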
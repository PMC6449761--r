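# PWM scanning of upstream windows, per-genome threshold calibration against
# the bounded fraction-of-genes rule, and rescue of weak (sub-threshold)
# sites supported by orthologous context.

# reverse-complement weight matrix: scoring the forward sequence with it
# equals scoring the reverse strand with the original motif
.rc_weights <- function(weights) {
  w <- weights[.complement_idx, ncol(weights):1, drop = FALSE]
  rownames(w) <- BASES
  w
}

#' Scan one upstream region with a motif
#'
#' Scores every window on both strands (forward strand only when the motif is
#' palindromic-symmetrized, to avoid duplicate reporting of the same physical
#' site). Positions are reported relative to the annotated gene start
#' (negative = upstream). Regions shorter than the motif yield an empty
#' result with a notice, not an error.
#'
#' @param motif a `motif`.
#' @param region an `upstream_region` (or bare string, in which case
#'   `gene_start_offset` is taken as 0).
#' @param sort sort hits by descending score (ties: smaller position first,
#'   then + strand). Default TRUE.
#' @return data.frame with columns position, strand, score.
#' @export
scan_region <- function(motif, region, sort = TRUE) {
  if (is.character(region))
    region <- list(sequence = region, gene_start_offset = 0L)
  v <- .seq_to_idx(region$sequence)
  if (length(v) < motif$length) {
    message("region shorter than motif (", length(v), " < ", motif$length,
            "): no hits")
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  fwd <- .score_vector(v, motif$weights)
  pos <- seq_along(fwd) - 1L - region$gene_start_offset
  out <- data.frame(position = pos, strand = "+", score = fwd,
                    stringsAsFactors = FALSE)
  if (!motif$palindromic) {
    rev <- .score_vector(v, .rc_weights(motif$weights))
    out <- rbind(out, data.frame(position = pos, strand = "-", score = rev,
                                 stringsAsFactors = FALSE))
  }
  if (sort)
    out <- out[order(-out$score, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-gene forward/reverse window scores for a whole genome (internal)
.genome_scores <- function(motif, gn, config, gene_ids = gn$genes$gene_id) {
  regions <- upstream_regions(gn, gene_ids, config)
  wrc <- if (motif$palindromic) NULL else .rc_weights(motif$weights)
  lapply(regions, function(r) {
    v <- .seq_to_idx(r$sequence)
    fwd <- .score_vector(v, motif$weights)
    list(fwd = fwd,
         rev = if (is.null(wrc)) NULL else .score_vector(v, wrc),
         offset = r$gene_start_offset)
  })
}

.best_of <- function(sc) {
  vals <- c(sc$fwd, sc$rev)
  if (length(vals) == 0) -Inf else max(vals)
}

#' Best window score per gene across a genome
#'
#' @param motif a `motif`.
#' @param gn a [genome()].
#' @param config a [scan_config()].
#' @return named numeric vector (gene_id -> best score; `-Inf` for regions
#'   shorter than the motif).
#' @export
gene_best_scores <- function(motif, gn, config = scan_config()) {
  sc <- .genome_scores(motif, gn, config)
  vapply(sc, .best_of, numeric(1))
}

# smallest observed-score threshold t with |{S >= t}| / n <= frac
.min_admissible <- function(scores, frac) {
  n <- length(scores)
  k <- floor(frac * n)
  if (k >= n) return(min(scores))
  vals <- sort(unique(scores))
  cnt_ge <- vapply(vals, function(v) sum(scores >= v), numeric(1))
  ok <- vals[cnt_ge <= k]
  if (length(ok) > 0) return(min(ok))
  # k == 0 (or all-tied): no observed score qualifies; sit just above the max
  max(scores) + 1e-9 * (abs(max(scores)) + 1)
}

#' Calibrate the score threshold of a motif across genomes
#'
#' For each genome the minimum admissible threshold is the smallest score t
#' such that the fraction of genes whose best window scores at least t does
#' not exceed `max_hit_fraction`. One threshold per factor is reported: the
#' maximum of the per-genome minima, i.e. the most permissive value feasible
#' in every genome simultaneously (per-genome minima are retained so a
#' per-genome reading remains recoverable). Training genes are audited, not
#' enforced: those whose best score falls below the final threshold are
#' listed as conflicts rather than silently admitted.
#'
#' @param motif a `motif`.
#' @param genomes list of [genome()] objects.
#' @param training_genes optional named list genome_id -> gene ids of genes
#'   expected to carry sites.
#' @param config a [scan_config()].
#' @return object of class `calibration_result`: tf_name, threshold,
#'   per_genome (data.frame genome_id, n_genes, min_admissible, hit_fraction),
#'   training_coverage, conflicts, best_scores (named list per genome).
#' @export
calibrate_threshold <- function(motif, genomes, training_genes = NULL,
                                config = scan_config()) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  const <- all(apply(motif$weights, 2, function(w) diff(range(w)) < 1e-12))
  if (const)
    stop("calibration impossible: motif has zero information (constant score)")
  best <- lapply(genomes, function(gn) gene_best_scores(motif, gn, config))
  names(best) <- vapply(genomes, `[[`, character(1), "genome_id")
  minima <- vapply(best, .min_admissible, numeric(1),
                   frac = config$max_hit_fraction)
  threshold <- max(minima)
  per_genome <- data.frame(
    genome_id = names(best),
    n_genes = vapply(best, length, integer(1)),
    min_admissible = minima,
    hit_fraction = vapply(best, function(s) mean(s >= threshold), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  coverage <- NA_real_
  conflicts <- data.frame(genome_id = character(0), gene_id = character(0),
                          score = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(training_genes)) {
    tr <- do.call(rbind, lapply(names(training_genes), function(g) {
      ids <- training_genes[[g]]
      data.frame(genome_id = g, gene_id = ids,
                 score = unname(best[[g]][ids]), stringsAsFactors = FALSE)
    }))
    coverage <- mean(tr$score >= threshold)
    conflicts <- tr[tr$score < threshold, , drop = FALSE]
    rownames(conflicts) <- NULL
  }
  structure(list(tf_name = motif$tf_name, threshold = threshold,
                 per_genome = per_genome, training_coverage = coverage,
                 conflicts = conflicts, best_scores = best),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> %s: threshold %.4f; hit fractions %s%s\n",
              x$tf_name, x$threshold,
              paste(sprintf("%s=%.3f", x$per_genome$genome_id,
                            x$per_genome$hit_fraction), collapse = ", "),
              if (!is.na(x$training_coverage))
                sprintf("; training coverage %.2f", x$training_coverage)
              else ""))
  invisible(x)
}

#' Scan genomes for candidate sites above the rescue floor
#'
#' Reports every window scoring at least `rescue_factor * threshold` in any
#' gene's upstream window, categorized "strong" (at or above the threshold)
#' or "weak_candidate" (below it, eligible for [rescue_weak_sites()]).
#' Deterministic ordering: genome, gene, descending score, position, strand.
#'
#' @param motif a `motif`.
#' @param genomes list of [genome()] objects.
#' @param calibration a `calibration_result` for this motif.
#' @param config a [scan_config()].
#' @return data.frame of site hits: tf_name, genome_id, gene_id, position,
#'   strand, score, score_ratio, category.
#' @export
scan_hits <- function(motif, genomes, calibration, config = scan_config()) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  t <- calibration$threshold
  floor_score <- config$rescue_factor * t
  rows <- list()
  for (gn in genomes) {
    sc <- .genome_scores(motif, gn, config)
    for (gene_id in names(sc)) {
      s <- sc[[gene_id]]
      for (strand in c("+", "-")) {
        vec <- if (strand == "+") s$fwd else s$rev
        if (is.null(vec)) next
        keep <- which(vec >= floor_score)
        if (length(keep) == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          tf_name = motif$tf_name, genome_id = gn$genome_id,
          gene_id = gene_id, position = keep - 1L - s$offset,
          strand = strand, score = vec[keep],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(tf_name = character(0), genome_id = character(0),
                      gene_id = character(0), position = integer(0),
                      strand = character(0), score = numeric(0),
                      score_ratio = numeric(0), category = character(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, rows)
  hits$score_ratio <- hits$score / t
  hits$category <- ifelse(hits$score >= t, "strong", "weak_candidate")
  hits <- hits[order(hits$genome_id, hits$gene_id, -hits$score,
                     hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Rescue weak sites supported by orthologous context
#'
#' A sub-threshold hit (score in `[rescue_factor * t, t)`) is considered for
#' rescue only when its gene's ortholog group already carries a strong hit in
#' at least one other genome -- the orthologous context in which weaker sites
#' were originally admitted. Within that context a weak hit is rescued when
#' (a) some orthologous gene in another genome has a strong hit whose
#' position relative to the gene start differs by at most
#' `position_tolerance`, or (b) no other hit in the same gene's upstream
#' region scores higher. Rescue never promotes a hit to strong and never
#' alters strong hits.
#'
#' @param hits data.frame from [scan_hits()] (strong + weak_candidate).
#' @param ortholog_table data.frame with columns group_id, genome_id, gene_id.
#' @param calibration a `calibration_result`.
#' @param config a [scan_config()].
#' @return the rescued subset of `hits` with category "weak_rescued" and an
#'   added `rescue_clause` column ("a", "b" or "ab").
#' @export
rescue_weak_sites <- function(hits, ortholog_table, calibration,
                              config = scan_config()) {
  empty <- cbind(hits[0, , drop = FALSE],
                 data.frame(rescue_clause = character(0)))
  if (nrow(hits) == 0) return(empty)
  key <- paste(hits$genome_id, hits$gene_id)
  okey <- paste(ortholog_table$genome_id, ortholog_table$gene_id)
  hits$group_id <- ortholog_table$group_id[match(key, okey)]
  strong <- hits[hits$category == "strong", , drop = FALSE]
  weak <- hits[hits$category == "weak_candidate", , drop = FALSE]
  if (nrow(weak) == 0) return(empty)
  out <- list()
  for (i in seq_len(nrow(weak))) {
    w <- weak[i, ]
    if (is.na(w$group_id)) next
    ortho_strong <- strong[!is.na(strong$group_id) &
                             strong$group_id == w$group_id &
                             strong$genome_id != w$genome_id, , drop = FALSE]
    if (nrow(ortho_strong) == 0) next
    clause_a <- any(abs(ortho_strong$position - w$position) <=
                      config$position_tolerance)
    same_region <- hits$genome_id == w$genome_id & hits$gene_id == w$gene_id
    clause_b <- !any(hits$score[same_region] > w$score)
    if (clause_a || clause_b) {
      w$category <- "weak_rescued"
      w$rescue_clause <- if (clause_a && clause_b) "ab" else
        if (clause_a) "a" else "b"
      out[[length(out) + 1L]] <- w
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$group_id <- NULL
  rownames(res) <- NULL
  res
}

#' Combine strong and rescued hits into the final site list
#'
#' @param hits data.frame from [scan_hits()].
#' @param rescued data.frame from [rescue_weak_sites()].
#' @return data.frame of strong and weak_rescued hits, with rescue_clause NA
#'   for strong hits.
#' @export
final_hits <- function(hits, rescued) {
  strong <- hits[hits$category == "strong", , drop = FALSE]
  if (nrow(strong) > 0) strong$rescue_clause <- NA_character_
  else strong$rescue_clause <- character(0)
  out <- rbind(strong, rescued)
  out <- out[order(out$genome_id, out$gene_id, -out$score, out$position,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
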
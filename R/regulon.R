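# Operon inference from intergenic distances, cross-genome persistence of
# operon organization, regulon assembly and operon extension, and detection
# of divergently transcribed gene pairs sharing a regulatory region.

#' Infer operons from same-strand gene runs
#'
#' Splits the coordinate-sorted gene list of each contig into maximal
#' same-strand runs wherever the intergenic gap (next start minus previous
#' end, computed on the contig and identical in transcription order) exceeds
#' `operon_max_gap`. Overlapping genes (negative gap) always merge. The
#' leader is the 5'-most gene in transcription order (leftmost for + runs,
#' rightmost for - runs).
#'
#' @param gn a [genome()].
#' @param config a [scan_config()] (uses `operon_max_gap`).
#' @return data.frame with one row per operon: operon_id, genome_id,
#'   contig_id, strand, n_genes, leader, and a list column `genes` holding
#'   gene ids in transcription order.
#' @export
infer_operons <- function(gn, config = scan_config()) {
  g <- gn$genes
  rows <- list()
  for (ctg in unique(g$contig_id)) {
    sub <- g[g$contig_id == ctg, , drop = FALSE]   # sorted by start
    n <- nrow(sub)
    if (n == 0) next
    brk <- logical(n)
    brk[1] <- TRUE
    if (n > 1) for (i in 2:n) {
      gap <- sub$start[i] - sub$end[i - 1]
      brk[i] <- sub$strand[i] != sub$strand[i - 1] | gap > config$operon_max_gap
    }
    run_id <- cumsum(brk)
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      strand <- sub$strand[idx[1]]
      ids <- sub$gene_id[idx]
      if (strand == "-") ids <- rev(ids)   # transcription order
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gn$genome_id, contig_id = ctg, strand = strand,
        n_genes = length(ids), leader = ids[1],
        genes = I(list(ids)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$operon_id <- sprintf("%s_op%03d", gn$genome_id, seq_len(nrow(out)))
  out[, c("operon_id", "genome_id", "contig_id", "strand", "n_genes",
          "leader", "genes")]
}

.gene_to_group <- function(ortholog_table) {
  stats::setNames(ortholog_table$group_id,
                  paste(ortholog_table$genome_id, ortholog_table$gene_id))
}

#' Cross-genome persistence of operon adjacencies
#'
#' An adjacency is an ordered pair of ortholog groups consecutive inside one
#' operon (in transcription order, computed on ortholog-group order so that
#' genome-specific unmapped genes inserted inside a conserved operon do not
#' break the flanking adjacency). An adjacency is supported when it occurs
#' inside operons of at least `min_genomes` genomes; unsupported adjacencies
#' split their operons for regulon-extension purposes.
#'
#' @param operons_by_genome list of [infer_operons()] results.
#' @param ortholog_table data.frame group_id / genome_id / gene_id.
#' @param min_genomes support requirement.
#' @return data.frame group_a, group_b, n_genomes, supported.
#' @export
check_operon_persistence <- function(operons_by_genome, ortholog_table,
                                     min_genomes = 3L) {
  g2g <- .gene_to_group(ortholog_table)
  adj <- list()
  for (ops in operons_by_genome) {
    genome_id <- ops$genome_id[1]
    for (r in seq_len(nrow(ops))) {
      groups <- unname(g2g[paste(genome_id, ops$genes[[r]])])
      groups <- groups[!is.na(groups)]
      if (length(groups) < 2) next
      for (i in seq_len(length(groups) - 1))
        adj[[length(adj) + 1L]] <- data.frame(
          genome_id = genome_id, group_a = groups[i], group_b = groups[i + 1],
          stringsAsFactors = FALSE)
    }
  }
  if (length(adj) == 0)
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_genomes = integer(0), supported = logical(0),
                      stringsAsFactors = FALSE))
  adj <- unique(do.call(rbind, adj))
  agg <- stats::aggregate(list(n_genomes = adj$genome_id),
                          by = list(group_a = adj$group_a,
                                    group_b = adj$group_b), FUN = length)
  agg$supported <- agg$n_genomes >= min_genomes
  agg[order(agg$group_a, agg$group_b), , drop = FALSE]
}

# genes reachable downstream of `from` (inclusive) in transcription order,
# stopping at the first unsupported adjacency (evaluated on group order)
.extend_downstream <- function(genes_in_order, from, genome_id, g2g,
                               supported_pairs) {
  i0 <- match(from, genes_in_order)
  out <- from
  prev_group <- unname(g2g[paste(genome_id, from)])
  if (i0 < length(genes_in_order)) for (i in (i0 + 1):length(genes_in_order)) {
    gid <- genes_in_order[i]
    grp <- unname(g2g[paste(genome_id, gid)])
    if (!is.na(prev_group) && !is.na(grp)) {
      if (!paste(prev_group, grp) %in% supported_pairs) break
    }
    out <- c(out, gid)
    if (!is.na(grp)) prev_group <- grp
  }
  out
}

#' Assemble a cross-genome regulon from calibrated site hits
#'
#' Core members are ortholog groups whose transcription-unit leader genes
#' carry a strong (or, by default, weak-rescued) hit in at least
#' `min_genomes` genomes. Hits upstream of operon-internal genes do not count
#' as core evidence -- they are reported as candidate internal transcription
#' units and serve as extension start points. Each supported member is
#' extended downstream through its operon, stopping at adjacencies that do
#' not persist across genomes. Groups with evidence in a single genome are
#' reported in a `singletons` side table, not as members.
#'
#' @param tf_name factor name.
#' @param hits final hit table ([final_hits()]): strong + weak_rescued.
#' @param ortholog_table data.frame group_id / genome_id / gene_id.
#' @param operons_by_genome list of [infer_operons()] results, one per genome.
#' @param config a [scan_config()].
#' @param strict if TRUE only strong hits establish core membership
#'   (weak-rescued hits then only supply per-genome evidence).
#' @return object of class `regulon`: tf_name, core (data.frame group_id,
#'   n_support_genomes, genomes), members (per-genome gene-level table with
#'   roles core/extended), singletons, internal_tu (hits on non-leader
#'   genes), evidence (leader hits used).
#' @export
assemble_regulon <- function(tf_name, hits, ortholog_table, operons_by_genome,
                             config = scan_config(), strict = FALSE) {
  g2g <- .gene_to_group(ortholog_table)
  hits <- hits[hits$tf_name == tf_name, , drop = FALSE]
  if (strict) hits <- hits[hits$category == "strong", , drop = FALSE]
  leaders <- unlist(lapply(operons_by_genome, function(ops)
    paste(ops$genome_id[1], ops$leader)))
  hkey <- paste(hits$genome_id, hits$gene_id)
  hits$group_id <- unname(g2g[hkey])
  hits$is_leader <- hkey %in% leaders
  leader_hits <- hits[hits$is_leader & !is.na(hits$group_id), , drop = FALSE]
  internal_tu <- hits[!hits$is_leader, , drop = FALSE]
  support <- unique(leader_hits[, c("group_id", "genome_id")])
  n_sup <- table(support$group_id)
  core_groups <- as.character(names(n_sup)[n_sup >= config$min_genomes])
  singleton_groups <- as.character(names(n_sup)[n_sup < config$min_genomes])
  core <- data.frame(
    group_id = core_groups,
    n_support_genomes = as.integer(n_sup[core_groups]),
    genomes = vapply(core_groups, function(g)
      paste(sort(support$genome_id[support$group_id == g]), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  core <- core[order(core$group_id), , drop = FALSE]
  persistence <- check_operon_persistence(operons_by_genome, ortholog_table,
                                          config$min_genomes)
  supported_pairs <- paste(persistence$group_a[persistence$supported],
                           persistence$group_b[persistence$supported])
  # extension: from every hit gene whose group is core, walk downstream
  members <- list()
  ext_hits <- hits[!is.na(hits$group_id) &
                     hits$group_id %in% core_groups, , drop = FALSE]
  for (ops in operons_by_genome) {
    genome_id <- ops$genome_id[1]
    gh <- unique(ext_hits$gene_id[ext_hits$genome_id == genome_id])
    for (r in seq_len(nrow(ops))) {
      starts <- intersect(ops$genes[[r]], gh)
      if (length(starts) == 0) next
      reached <- unique(unlist(lapply(starts, .extend_downstream,
                                      genes_in_order = ops$genes[[r]],
                                      genome_id = genome_id, g2g = g2g,
                                      supported_pairs = supported_pairs)))
      reached <- ops$genes[[r]][ops$genes[[r]] %in% reached]  # keep order
      members[[length(members) + 1L]] <- data.frame(
        genome_id = genome_id, gene_id = reached,
        group_id = unname(g2g[paste(genome_id, reached)]),
        operon_id = ops$operon_id[r],
        role = ifelse(reached %in% starts, "core", "extended"),
        stringsAsFactors = FALSE)
    }
  }
  members <- if (length(members) > 0) do.call(rbind, members) else
    data.frame(genome_id = character(0), gene_id = character(0),
               group_id = character(0), operon_id = character(0),
               role = character(0), stringsAsFactors = FALSE)
  members <- members[order(members$genome_id, members$operon_id,
                           members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  singletons <- leader_hits[leader_hits$group_id %in% singleton_groups, ,
                            drop = FALSE]
  rownames(singletons) <- NULL
  structure(list(tf_name = tf_name, core = core, members = members,
                 singletons = singletons, internal_tu = internal_tu,
                 evidence = leader_hits, persistence = persistence),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: %d core group(s), %d member gene(s), %d singleton candidate(s)\n",
              x$tf_name, nrow(x$core), nrow(x$members), nrow(x$singletons)))
  invisible(x)
}

# contig-coordinate interval of a gene-relative hit
.hit_contig_interval <- function(gene_row, position, width) {
  if (gene_row$strand == "+") {
    lo <- gene_row$start + position
  } else {
    lo <- gene_row$end - position - width
  }
  c(lo, lo + width)
}

#' Detect divergently transcribed gene pairs sharing a regulatory region
#'
#' Finds adjacent opposite-strand head-to-head gene pairs (left gene on the
#' minus strand, right gene on the plus strand, promoters facing the shared
#' intergenic segment) whose upstream scan windows overlap. Any hit falling
#' inside the shared segment is attributed to both genes of the pair.
#'
#' @param gn a [genome()].
#' @param hits optional hit table with motif-length hits (`site_width` used
#'   to place them on the contig).
#' @param config a [scan_config()].
#' @param site_width width of a site (nt), required when `hits` given.
#' @return data.frame gene_a (minus-strand gene), gene_b, contig_id,
#'   overlap_start, overlap_end, n_shared_hits, and list column shared_hits.
#' @export
detect_divergons <- function(gn, hits = NULL, config = scan_config(),
                             site_width = NULL) {
  g <- gn$genes
  out <- list()
  for (ctg in unique(g$contig_id)) {
    sub <- g[g$contig_id == ctg, , drop = FALSE]
    clen <- nchar(gn$contigs[[ctg]])
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) {
      a <- sub[i, ]; b <- sub[i + 1, ]
      if (!(a$strand == "-" && b$strand == "+")) next
      # oriented upstream windows, clipped
      a_lo <- max(0L, a$end - config$downstream_span)
      a_hi <- min(clen, a$end + config$upstream_span)
      b_lo <- max(0L, b$start - config$upstream_span)
      b_hi <- min(clen, b$start + config$downstream_span)
      lo <- max(a_lo, b_lo); hi <- min(a_hi, b_hi)
      if (lo >= hi) next
      shared <- NULL
      if (!is.null(hits) && nrow(hits) > 0) {
        stopifnot(!is.null(site_width))
        cand <- hits[hits$genome_id == gn$genome_id &
                       hits$gene_id %in% c(a$gene_id, b$gene_id), ,
                     drop = FALSE]
        if (nrow(cand) > 0) {
          cs <- vapply(seq_len(nrow(cand)), function(r) {
            grow <- if (cand$gene_id[r] == a$gene_id) a else b
            .hit_contig_interval(grow, cand$position[r], site_width)[1]
          }, numeric(1))
          cand$contig_start <- as.integer(cs)
          keep <- cs >= lo & cs + site_width <= hi
          shared <- cand[keep, , drop = FALSE]
          # the same physical site is seen from both genes; report it once
          shared <- shared[!duplicated(shared$contig_start), , drop = FALSE]
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_a = a$gene_id, gene_b = b$gene_id, contig_id = ctg,
        overlap_start = lo, overlap_end = hi,
        n_shared_hits = if (is.null(shared)) 0L else nrow(shared),
        shared_hits = I(list(shared)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      contig_id = character(0), overlap_start = integer(0),
                      overlap_end = integer(0), n_shared_hits = integer(0),
                      shared_hits = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
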
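# Synthetic multi-genome datasets with planted regulons and full ground
# truth. The generator emulates the structure the comparative procedure
# assumes: orthologous gene complements, conserved operon organization
# (same-strand runs with short intergenic gaps), divergently transcribed
# junctions, and upstream regions derived from a common ancestor so that
# planted sites are conserved verbatim against a diverged background.

#' Specification of a planted transcription-factor regulon
#'
#' @param tf_name factor name.
#' @param consensus IUPAC consensus the planted sites instantiate.
#' @param n_target_groups number of ortholog groups (operon leaders) that
#'   receive sites.
#' @param sites_per_region sites planted per upstream region; multiple sites
#'   are spaced three helical turns apart (cooperative-binding arrangement).
#' @param weak_fraction proportion of planted site instances weakened to
#'   score just below the calibrated threshold (the rescue band).
#' @param site_position_range interval (nt, relative to the gene start,
#'   negative = upstream) from which the most-downstream site start of each
#'   region is drawn.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(tf_name, consensus, n_target_groups,
                       sites_per_region = 1L, weak_fraction = 0,
                       site_position_range = c(-220L, -50L)) {
  stopifnot(nchar(consensus) > 0, n_target_groups >= 1,
            sites_per_region >= 1, weak_fraction >= 0, weak_fraction <= 1,
            length(site_position_range) == 2,
            site_position_range[1] <= site_position_range[2])
  .check_iupac(consensus)
  structure(list(tf_name = tf_name, consensus = consensus,
                 n_target_groups = as.integer(n_target_groups),
                 sites_per_region = as.integer(sites_per_region),
                 weak_fraction = weak_fraction,
                 site_position_range = as.integer(site_position_range)),
            class = "plant_spec")
}

.random_seq_int <- function(n, gc) {
  # 1..4 = A,C,G,T with P(C)=P(G)=gc/2
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.int_to_seq <- function(v) paste(BASES[v], collapse = "")

# substitute positions of an integer-coded sequence at per-position rates;
# substituted bases are drawn uniformly from the three other bases
.mutate_int <- function(v, rates) {
  hit <- which(stats::runif(length(v)) < rates)
  if (length(hit) > 0) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- ((v[hit] - 1L + shift) %% 4L) + 1L
  }
  v
}

# contig interval [lo, hi) of an oriented gene-relative interval [p, p+w)
.oriented_to_contig <- function(start, end, strand, p, w) {
  if (strand == "+") c(start + p, start + p + w) else c(end - p - w, end - p)
}

# write `s` (gene-oriented) into contig character vector at oriented pos p
.write_site <- function(contig_int, gene, p, s_int) {
  iv <- .oriented_to_contig(gene$start, gene$end, gene$strand, p,
                            length(s_int))
  piece <- if (gene$strand == "+") s_int else rev(5L - s_int)
  contig_int[(iv[1] + 1):iv[2]] <- piece
  contig_int
}

.read_site <- function(contig_int, gene, p, w) {
  iv <- .oriented_to_contig(gene$start, gene$end, gene$strand, p, w)
  piece <- contig_int[(iv[1] + 1):iv[2]]
  if (gene$strand == "-") piece <- rev(5L - piece)
  piece
}

# choose mismatch combination bringing score of `s_int` into [lo, hi],
# closest to `target`; enumerates up to 4 simultaneous substitutions
.weaken_site <- function(s_int, weights, lo, hi, target) {
  L <- length(s_int)
  drops <- lapply(seq_len(L), function(j) {
    cur <- weights[s_int[j], j]
    alts <- setdiff(1:4, s_int[j])
    stats::setNames(cur - weights[alts, j], alts)
  })
  score0 <- sum(weights[cbind(s_int, seq_len(L))])
  candidates <- list()
  for (k in 1:4) {
    combos <- utils::combn(L, k)
    for (ci in seq_len(ncol(combos))) {
      pos <- combos[, ci]
      # all 3^k alt-base assignments for this position set, vectorized
      total <- drops[[pos[1]]]
      sel <- matrix(seq_len(3), ncol = 1)
      if (k > 1) for (m in 2:k) {
        total <- as.vector(outer(total, drops[[pos[m]]], "+"))
        sel <- cbind(sel[rep(seq_len(nrow(sel)), times = 3), , drop = FALSE],
                     rep(seq_len(3), each = nrow(sel)))
      }
      sc <- score0 - total
      for (i in which(sc >= lo & sc <= hi))
        candidates[[length(candidates) + 1L]] <- list(
          pos = pos, alt = vapply(seq_len(k), function(m)
            as.integer(names(drops[[pos[m]]])[sel[i, m]]), integer(1)))
    }
    if (length(candidates) > 0) break
  }
  if (length(candidates) == 0) return(NULL)
  # sample among admissible minimal-mismatch combinations so that weakened
  # copies of one motif do not all share a mismatch pattern
  best <- candidates[[sample.int(length(candidates), 1)]]
  out <- s_int
  out[best$pos] <- best$alt
  out
}

#' Generate a synthetic multi-genome dataset with planted regulons
#'
#' Builds one ancestral contig (i.i.d. background at the requested GC
#' content) laid out as operonic runs of ortholog groups with short
#' intra-run gaps and long inter-run gaps, plants exact instantiations of
#' each factor's consensus upstream of randomly chosen run-leader groups,
#' then derives each genome as an independently substituted copy of the
#' ancestor (configurable rates in intergenic and coding sequence, verbatim
#' inside planted sites). Gene layout is shared across genomes, so operon
#' organization persists and planted site positions are conserved. A
#' `weak_fraction` of site instances is weakened by minimal base
#' substitutions until they score inside the rescue band just below the
#' calibrated detection threshold (calibration is re-run after weakening).
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_groups ortholog groups (one gene per group per genome).
#' @param plants list of [plant_spec()] objects.
#' @param seed integer seed; the dataset is byte-identical for equal inputs.
#' @param gc_content background GC proportion in (0, 1).
#' @param operon_spec list: run_lengths, run_length_probs, intra_gap_range
#'   (< operon gap limit), inter_gap_range (> operon gap limit, long enough
#'   that a leader's scan window never reaches the neighboring run's sites),
#'   gene_length_range.
#' @param noncoding_substitution_rate per-base substitution probability from
#'   the ancestor in intergenic sequence.
#' @param coding_substitution_rate likewise inside genes.
#' @param site_substitution_rate likewise inside planted sites (default 0:
#'   sites copied verbatim).
#' @param config a [scan_config()].
#' @param weak_band target score band for weakened sites, as fractions of
#'   the calibrated threshold; must lie inside `[rescue_factor, 1)`.
#' @param calibration_iterations weaken/recalibrate rounds.
#' @return object of class `synthetic_dataset`: list with `genomes` (named
#'   list of [genome()]), `ortholog_table`, `truth` (class
#'   `synthetic_truth`: planted_sites, regulon_membership, operon_layout),
#'   `plants`, `config`, `seed`, `generator` (internal motifs/thresholds).
#' @export
generate_dataset <- function(n_genomes = 5L, n_groups = 200L, plants = list(),
                             seed = 1L, gc_content = 0.5,
                             operon_spec = list(),
                             noncoding_substitution_rate = 0.3,
                             coding_substitution_rate = 0.1,
                             site_substitution_rate = 0,
                             config = scan_config(),
                             weak_band = c(0.92, 0.98),
                             calibration_iterations = 2L) {
  stopifnot(n_genomes >= 2, n_groups >= 2, gc_content > 0, gc_content < 1,
            weak_band[1] >= config$rescue_factor, weak_band[2] < 1)
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  spec <- utils::modifyList(list(
    run_lengths = 1:3, run_length_probs = c(0.55, 0.30, 0.15),
    intra_gap_range = c(20L, 150L), inter_gap_range = c(600L, 800L),
    gene_length_range = c(600L, 1500L)), operon_spec)
  if (spec$intra_gap_range[2] > config$operon_max_gap)
    stop("intra-run gaps must stay below operon_max_gap")
  if (spec$inter_gap_range[1] <= config$operon_max_gap)
    stop("inter-run gaps must exceed operon_max_gap")
  for (p in plants) {
    L <- nchar(p$consensus)
    span_up <- -(p$site_position_range[1] -
                   32L * (p$sites_per_region - 1L))
    if (span_up > config$upstream_span ||
        p$site_position_range[2] + L > config$downstream_span)
      stop("infeasible plant: sites of '", p$tf_name,
           "' do not fit the scan window")
    if (p$sites_per_region > 1 && L >= 32)
      stop("infeasible plant: consensus too long for 3-turn site spacing")
  }
  set.seed(seed)

  ## operonic layout, shared across genomes
  lens <- integer(0)
  while (sum(lens) < n_groups)
    lens <- c(lens, sample(spec$run_lengths, 1, prob = spec$run_length_probs))
  lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n_groups)
  lens <- lens[lens > 0]
  run_strand <- sample(c("+", "-"), length(lens), replace = TRUE)
  group_ids <- sprintf("g%03d", seq_len(n_groups))
  gene_len <- sample(spec$gene_length_range[1]:spec$gene_length_range[2],
                     n_groups, replace = TRUE)
  pos <- 0L
  gidx <- 0L
  gene_tab <- list()
  run_of_group <- integer(n_groups)
  for (r in seq_along(lens)) {
    pos <- pos + sample(spec$inter_gap_range[1]:spec$inter_gap_range[2], 1)
    for (j in seq_len(lens[r])) {
      gidx <- gidx + 1L
      gene_tab[[gidx]] <- data.frame(
        group_id = group_ids[gidx], start = pos, end = pos + gene_len[gidx],
        strand = run_strand[r], run = r, stringsAsFactors = FALSE)
      run_of_group[gidx] <- r
      pos <- pos + gene_len[gidx]
      if (j < lens[r])
        pos <- pos + sample(spec$intra_gap_range[1]:spec$intra_gap_range[2], 1)
    }
  }
  pos <- pos + sample(spec$inter_gap_range[1]:spec$inter_gap_range[2], 1)
  contig_len <- pos
  layout <- do.call(rbind, gene_tab)

  # run membership and leaders (transcription order)
  runs <- lapply(seq_along(lens), function(r) {
    ids <- layout$group_id[layout$run == r]
    if (run_strand[r] == "-") rev(ids) else ids
  })
  leaders <- vapply(runs, `[`, character(1), 1)

  ## choose target leader groups per plant and plant into the ancestor
  anc <- .random_seq_int(contig_len, gc_content)
  avail <- leaders
  planted <- list()
  for (p in plants) {
    if (length(avail) < p$n_target_groups)
      stop("not enough operon leaders for plant '", p$tf_name, "'")
    targets <- sample(avail, p$n_target_groups)
    avail <- setdiff(avail, targets)
    L <- nchar(p$consensus)
    for (grp in targets) {
      grow <- layout[layout$group_id == grp, ]
      p0 <- sample(p$site_position_range[1]:p$site_position_range[2], 1)
      starts <- p0 - 32L * ((p$sites_per_region - 1L):0L)
      for (si in seq_along(starts)) {
        inst <- instantiate_consensus(p$consensus)
        strand <- sample(c("+", "-"), 1)
        s_int <- .seq_to_idx(if (strand == "+") inst else revcomp(inst))
        anc <- .write_site(anc, grow, starts[si], s_int)
        planted[[length(planted) + 1L]] <- data.frame(
          tf_name = p$tf_name, group_id = grp, site_index = si,
          position = starts[si], strand = strand, instantiation = inst,
          width = L, stringsAsFactors = FALSE)
      }
    }
  }
  planted <- if (length(planted) > 0) do.call(rbind, planted) else
    data.frame(tf_name = character(0), group_id = character(0),
               site_index = integer(0), position = integer(0),
               strand = character(0), instantiation = character(0),
               width = integer(0), stringsAsFactors = FALSE)

  ## substitution-rate mask
  rates <- rep(noncoding_substitution_rate, contig_len)
  for (i in seq_len(nrow(layout)))
    rates[(layout$start[i] + 1):layout$end[i]] <- coding_substitution_rate
  for (i in seq_len(nrow(planted))) {
    grow <- layout[layout$group_id == planted$group_id[i], ]
    iv <- .oriented_to_contig(grow$start, grow$end, grow$strand,
                              planted$position[i], planted$width[i])
    rates[(iv[1] + 1):iv[2]] <- site_substitution_rate
  }

  ## derive genomes
  genome_ids <- sprintf("G%d", seq_len(n_genomes))
  contigs_int <- lapply(genome_ids, function(g) .mutate_int(anc, rates))
  names(contigs_int) <- genome_ids
  make_genome <- function(gid) {
    genes <- data.frame(
      gene_id = paste0(gid, "_", layout$group_id),
      contig_id = "contig1", start = layout$start, end = layout$end,
      strand = layout$strand, locus_tag = paste0(gid, "_", layout$group_id),
      product = ifelse(layout$group_id %in% planted$group_id,
                       "planted regulon target", "hypothetical protein"),
      stringsAsFactors = FALSE)
    genome(gid, c(contig1 = .int_to_seq(contigs_int[[gid]])), genes)
  }
  genomes <- lapply(genome_ids, make_genome)
  names(genomes) <- genome_ids

  ortholog_table <- do.call(rbind, lapply(genome_ids, function(gid)
    data.frame(group_id = layout$group_id, genome_id = gid,
               gene_id = paste0(gid, "_", layout$group_id),
               stringsAsFactors = FALSE)))
  ortholog_table <- ortholog_table[order(ortholog_table$group_id,
                                         ortholog_table$genome_id), ]
  rownames(ortholog_table) <- NULL

  ## per-instance truth (site per genome), weak designation and targeting
  truth_sites <- list()
  generator <- list()
  for (p in plants) {
    psites <- planted[planted$tf_name == p$tf_name, , drop = FALSE]
    inst_tab <- expand.grid(row = seq_len(nrow(psites)),
                            genome_id = genome_ids,
                            stringsAsFactors = FALSE)
    inst_tab$category <- "strong"
    n_weak <- round(p$weak_fraction * nrow(inst_tab))
    if (n_weak > 0) {
      cap <- max(0L, n_genomes - config$min_genomes)
      ord <- sample(seq_len(nrow(inst_tab)))
      weak_per_group <- stats::setNames(
        integer(length(unique(psites$group_id))), unique(psites$group_id))
      chosen <- integer(0)
      for (i in ord) {
        if (length(chosen) >= n_weak) break
        grp <- psites$group_id[inst_tab$row[i]]
        if (weak_per_group[grp] < cap) {
          chosen <- c(chosen, i)
          weak_per_group[grp] <- weak_per_group[grp] + 1L
        }
      }
      inst_tab$category[chosen] <- "weak"
    }
    # one site copy per genome, matching the training-set size a scan
    # pipeline harvesting these sites across genomes would see, so that the
    # weak-site score band transfers to downstream calibration
    motif <- build_pwm(rep(psites$instantiation, n_genomes),
                       tf_name = p$tf_name,
                       background = genome_background(genomes))
    if (motif$palindromic) motif <- symmetrize(motif)
    threshold <- NA_real_
    weak_rows <- which(inst_tab$category == "weak")
    iterations <- if (length(weak_rows) > 0) calibration_iterations else 1L
    for (iter in seq_len(iterations)) {
      cal <- calibrate_threshold(motif, genomes, config = config)
      threshold <- cal$threshold
      if (length(weak_rows) == 0) break
      lo <- weak_band[1] * threshold
      hi <- weak_band[2] * threshold
      target <- mean(c(lo, hi))
      for (i in weak_rows) {
        ps <- psites[inst_tab$row[i], ]
        gid <- inst_tab$genome_id[i]
        grow <- layout[layout$group_id == ps$group_id, ]
        s0 <- .seq_to_idx(ps$instantiation)   # weaken from the strong copy
        wk <- .weaken_site(s0, motif$weights, lo, hi, target)
        if (is.null(wk)) next  # no reachable combination; site stays strong
        oriented <- if (ps$strand == "+") wk else rev(5L - wk)
        contigs_int[[gid]] <- .write_site(contigs_int[[gid]], grow,
                                          ps$position, oriented)
      }
      genomes <- lapply(genome_ids, make_genome)
      names(genomes) <- genome_ids
    }
    if (length(weak_rows) > 0) {
      # record the threshold valid for the final (weakened) genomes
      threshold <- calibrate_threshold(motif, genomes,
                                       config = config)$threshold
      # weakening can overshoot or the threshold can drift between rounds;
      # the truth table records the realized category under the final
      # threshold (a designated-weak copy scoring at/above it is strong;
      # one below the rescue band is marked lost)
      for (i in weak_rows) {
        ps <- psites[inst_tab$row[i], ]
        grow <- layout[layout$group_id == ps$group_id, ]
        piece <- .int_to_seq(.read_site(contigs_int[[inst_tab$genome_id[i]]],
                                        grow, ps$position, ps$width))
        sc <- score_window(motif,
                           if (ps$strand == "+") piece else revcomp(piece))
        inst_tab$category[i] <-
          if (sc >= threshold) "strong"
          else if (sc >= config$rescue_factor * threshold) "weak"
          else "lost"
      }
    }
    generator[[p$tf_name]] <- list(motif = motif, threshold = threshold)
    for (i in seq_len(nrow(inst_tab))) {
      ps <- psites[inst_tab$row[i], ]
      gid <- inst_tab$genome_id[i]
      grow <- layout[layout$group_id == ps$group_id, ]
      # gene-oriented realized string; report it in the site's own strand
      piece <- .int_to_seq(.read_site(contigs_int[[gid]], grow,
                                      ps$position, ps$width))
      site_seq <- if (ps$strand == "+") piece else revcomp(piece)
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        tf_name = p$tf_name, genome_id = gid,
        gene_id = paste0(gid, "_", ps$group_id), group_id = ps$group_id,
        site_index = ps$site_index, position = ps$position,
        strand = ps$strand, instantiation = ps$instantiation,
        sequence = site_seq,
        category = inst_tab$category[i], stringsAsFactors = FALSE)
    }
  }
  truth_sites <- if (length(truth_sites) > 0) do.call(rbind, truth_sites) else
    data.frame()
  membership <- lapply(plants, function(p)
    sort(unique(planted$group_id[planted$tf_name == p$tf_name])))
  names(membership) <- vapply(plants, `[[`, character(1), "tf_name")
  layout_by_genome <- lapply(genome_ids, function(gid)
    lapply(runs, function(g) paste0(gid, "_", g)))
  names(layout_by_genome) <- genome_ids
  truth <- structure(list(planted_sites = truth_sites,
                          regulon_membership = membership,
                          operon_layout = layout_by_genome),
                     class = "synthetic_truth")
  structure(list(genomes = genomes, ortholog_table = ortholog_table,
                 truth = truth, plants = plants, config = config,
                 seed = seed, generator = generator),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genomes x %d genes, %d planted site instance(s), seed %d\n",
              length(x$genomes), nrow(x$genomes[[1]]$genes),
              nrow(x$truth$planted_sites), x$seed))
  invisible(x)
}

#' Plant a site shared by a divergently transcribed gene pair
#'
#' The two genes must be adjacent on one contig, on opposite strands with
#' their starts facing away from the shared intergenic region (left gene on
#' the minus strand, right gene on the plus strand). One instantiation of
#' the consensus is written into the intergenic region; by default at the
#' midpoint between the two gene starts, where it falls inside both genes'
#' upstream windows whenever they are close enough.
#'
#' @param gn a [genome()].
#' @param gene_a,gene_b the divergent gene pair (order free).
#' @param consensus IUPAC consensus to instantiate.
#' @param position optional site start relative to `gene_a`'s start
#'   (oriented, negative = upstream); default midpoint.
#' @param config a [scan_config()].
#' @return list with `genome` (modified), and `site`: data.frame with the
#'   planted sequence, contig interval, positions relative to both genes and
#'   flags saying whether it lies inside each gene's scan window.
#' @export
plant_divergon <- function(gn, gene_a, gene_b, consensus, position = NULL,
                           config = scan_config()) {
  a <- .gene_row(gn, gene_a)
  b <- .gene_row(gn, gene_b)
  if (a$contig_id != b$contig_id)
    stop("layout error: genes on different contigs")
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  between <- gn$genes$contig_id == a$contig_id &
    gn$genes$start >= left$end & gn$genes$end <= right$start
  if (any(between)) stop("layout error: genes are not adjacent")
  if (!(left$strand == "-" && right$strand == "+"))
    stop("layout error: genes are not divergently transcribed (heads apart)")
  L <- nchar(consensus)
  inst <- instantiate_consensus(consensus)
  # position relative to gene_a (oriented); default: site centered midway
  # between the two gene starts (left's start is its end coordinate)
  if (is.null(position)) {
    mid <- (left$end + right$start) %/% 2
    contig_lo <- mid - L %/% 2
  } else {
    iv <- .oriented_to_contig(a$start, a$end, a$strand, position, L)
    contig_lo <- iv[1]
  }
  if (contig_lo < left$end || contig_lo + L > right$start)
    stop("layout error: site does not fit the shared intergenic region")
  contig <- gn$contigs[[a$contig_id]]
  substr(contig, contig_lo + 1, contig_lo + L) <- inst
  gn$contigs[[a$contig_id]] <- contig
  rel <- function(g) {
    if (g$strand == "+") contig_lo - g$start else g$end - contig_lo - L
  }
  in_win <- function(p) p >= -config$upstream_span &&
    p + L <= config$downstream_span
  pa <- rel(a); pb <- rel(b)
  list(genome = gn,
       site = data.frame(sequence = inst, contig_id = a$contig_id,
                         contig_start = contig_lo, contig_end = contig_lo + L,
                         gene_a = a$gene_id, position_a = pa,
                         in_window_a = in_win(pa),
                         gene_b = b$gene_id, position_b = pb,
                         in_window_b = in_win(pb),
                         stringsAsFactors = FALSE))
}
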
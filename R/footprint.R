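# Phylogenetic footprinting: star multiple alignment of orthologous upstream
# regions and calling of runs of conserved columns as candidate site seeds.
# Rationale: binding sites are more conserved than intergenic background, so
# consecutive near-identical columns in an alignment of orthologous upstream
# regions mark candidate sites.

.pairwise_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE)
    cache
  }
})

# parse one global pairwise alignment of `other` against `center` into
# per-slot insertions (slot s = before center base s+1; slot n = after last)
# and the character carried by `other` at each center base.
.parse_vs_center <- function(other_aln, center_aln) {
  oc <- strsplit(other_aln, "", fixed = TRUE)[[1]]
  cc <- strsplit(center_aln, "", fixed = TRUE)[[1]]
  n_center <- sum(cc != "-")
  ins <- vector("list", n_center + 1L)
  for (s in seq_len(n_center + 1L)) ins[[s]] <- character(0)
  at_base <- character(n_center)
  slot <- 1L
  for (k in seq_along(cc)) {
    if (cc[k] == "-") {
      ins[[slot]] <- c(ins[[slot]], oc[k])
    } else {
      at_base[slot] <- oc[k]
      slot <- slot + 1L
    }
  }
  list(ins = ins, at_base = at_base)
}

#' Star multiple alignment of orthologous upstream regions
#'
#' Globally aligns every region to the longest region (match +1, mismatch -1,
#' gap opening -3, gap extension -1; a gap of length L costs 3 + L) with
#' \code{Biostrings::pairwiseAlignment}, then merges the pairwise alignments on
#' the center sequence's coordinates ("once a gap, always a gap"). Upstream
#' regions of orthologous genes are short and closely related, for which a
#' star alignment is adequate; the conserved-window caller downstream
#' tolerates suboptimal columns.
#'
#' @param regions named character vector or list of `upstream_region` objects
#'   (>= 2), names identifying the source genomes.
#' @param group_id identifier of the ortholog group.
#' @return object of class `region_alignment`: list with `group_id`, `rows`
#'   (named gapped sequences, equal length) and `n_columns`.
#' @export
align_regions <- function(regions, group_id = "group") {
  if (is.list(regions) && all(vapply(regions, inherits, TRUE, "upstream_region")))
    regions <- vapply(regions, function(r) r$sequence, character(1))
  regions <- unlist(regions)
  if (length(regions) < 2)
    stop("degenerate input: footprinting needs >= 2 orthologous regions")
  if (any(nchar(regions) == 0)) stop("empty region")
  if (is.null(names(regions)))
    names(regions) <- paste0("row", seq_along(regions))
  ci <- which.max(nchar(regions))
  center <- regions[[ci]]
  others <- regions[-ci]
  n_center <- nchar(center)
  parsed <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = s, subject = center, type = "global",
      substitutionMatrix = .pairwise_submat(),
      gapOpening = 3, gapExtension = 1)
    .parse_vs_center(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)))
  })
  ins_len <- matrix(0L, nrow = length(parsed), ncol = n_center + 1L)
  for (i in seq_along(parsed))
    ins_len[i, ] <- lengths(parsed[[i]]$ins)
  merged_ins <- if (length(parsed) > 0) apply(ins_len, 2, max) else
    integer(n_center + 1L)
  build_row <- function(ins, at_base) {
    parts <- character(0)
    for (s in seq_len(n_center + 1L)) {
      pad <- strrep("-", merged_ins[s] - length(ins[[s]]))
      parts <- c(parts, paste(ins[[s]], collapse = ""), pad,
                 if (s <= n_center) at_base[s] else "")
    }
    paste(parts, collapse = "")
  }
  center_row <- build_row(rep(list(character(0)), n_center + 1L),
                          strsplit(center, "", fixed = TRUE)[[1]])
  rows <- c(stats::setNames(list(center_row), names(regions)[ci]),
            lapply(parsed, function(p) build_row(p$ins, p$at_base)))
  rows <- unlist(rows)[names(regions)]   # restore input order
  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(group_id = group_id, rows = rows,
                 n_columns = nchar(rows[[1]])),
            class = "region_alignment")
}

#' @export
print.region_alignment <- function(x, ...) {
  cat(sprintf("<region_alignment> %s: %d rows x %d columns\n", x$group_id,
              length(x$rows), x$n_columns))
  invisible(x)
}

#' Call conserved windows in a region alignment
#'
#' Reports maximal runs of at least `min_window` consecutive gapless columns
#' whose per-column identity (modal base frequency over rows) is at least
#' `min_identity`. Gap columns break windows: a site interrupted by an indel
#' is not a clean seed. Maximal runs are disjoint and sorted by column start.
#' The defaults (0.9, 10 nt) call a verbatim-conserved 14 nt site while
#' leaving ~30\%-diverged background uncalled.
#'
#' @param alignment a `region_alignment`.
#' @param min_identity minimum per-column modal base frequency.
#' @param min_window minimum run length (columns).
#' @return data.frame with one row per window: group_id, col_start, col_end
#'   (1-based, inclusive), width, mean_identity, and per-row 0-based ungapped
#'   start offsets in a list column `row_offsets`.
#' @export
conserved_windows <- function(alignment, min_identity = 0.9, min_window = 10) {
  rows <- alignment$rows
  if (length(rows) < 2) stop("alignment must have >= 2 rows")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  nc <- ncol(mat)
  gapless <- colSums(mat == "-") == 0
  identity <- vapply(seq_len(nc), function(j) {
    if (!gapless[j]) return(0)
    max(table(mat[, j])) / nrow(mat)
  }, numeric(1))
  ok <- gapless & identity >= min_identity
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_window)
  out <- lapply(keep, function(k) {
    cs <- starts[k]; ce <- ends[k]
    offsets <- vapply(seq_along(rows), function(i) {
      sum(mat[i, seq_len(cs - 1L)] != "-")
    }, integer(1))
    names(offsets) <- names(rows)
    data.frame(group_id = alignment$group_id, col_start = cs, col_end = ce,
               width = ce - cs + 1L,
               mean_identity = mean(identity[cs:ce]),
               row_offsets = I(list(offsets)), stringsAsFactors = FALSE)
  })
  if (length(out) == 0)
    return(data.frame(group_id = character(0), col_start = integer(0),
                      col_end = integer(0), width = integer(0),
                      mean_identity = numeric(0),
                      row_offsets = I(list()), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# majority consensus (ties -> first base) of equal-length site strings
.majority_consensus <- function(sites) {
  mat <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  paste(apply(mat, 2, function(col) names(which.max(table(col)))),
        collapse = "")
}

.mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Harvest a PWM training set from conserved footprint windows
#'
#' Extracts the per-row ungapped subsequences of conserved windows called
#' across several ortholog groups and pools them into one training set.
#' Window lengths vary by chance extension of conservation into flanks, so
#' only windows of the modal width are kept (longer ones are trimmed to the
#' centered modal width when fewer than two windows have it). Each window's
#' sites are included in the orientation (forward or reverse complement) that
#' better matches the majority consensus of the sites pooled so far, so that
#' sites planted or found on either strand train a single motif.
#'
#' @param windows data.frame from [conserved_windows()] (rows from one or
#'   several groups row-bound together).
#' @param alignments named list of `region_alignment` objects, names matching
#'   `windows$group_id`.
#' @param tf_name name for the resulting [site_set()].
#' @return a [site_set()] with provenance (group, genome/row, offset).
#' @export
sites_from_windows <- function(windows, alignments, tf_name = "TF") {
  if (nrow(windows) == 0) stop("no conserved windows to harvest")
  tab <- table(windows$width)
  # modal width; ties broken toward the widest (fragments of a site broken
  # by a diverged copy are shorter than the clean windows)
  modal <- max(as.integer(names(tab)[tab == max(tab)]))
  use <- windows[windows$width >= modal, , drop = FALSE]
  # windows sharing the modal width anchor the register; wider windows are
  # trimmed at the offset (and orientation) that best matches them
  use <- use[order(use$width != modal, use$group_id), , drop = FALSE]
  seqs <- character(0)
  prov <- list()
  for (r in seq_len(nrow(use))) {
    aln <- alignments[[use$group_id[r]]]
    ungapped <- gsub("-", "", aln$rows, fixed = TRUE)
    offs <- use$row_offsets[[r]]
    w <- use$width[r]
    pick <- function(lead) vapply(seq_along(ungapped), function(i) {
      substr(ungapped[i], offs[i] + lead + 1L, offs[i] + lead + modal)
    }, character(1))
    if (length(seqs) == 0) {
      lead <- (w - modal) %/% 2
      group_sites <- pick(lead)
    } else {
      cons <- .majority_consensus(seqs)
      best <- NULL
      best_d <- Inf
      best_lead <- 0L
      for (lead in 0:(w - modal)) {
        cand <- pick(lead)
        for (orient in c("fwd", "rev")) {
          cc <- if (orient == "fwd") cand else revcomp(cand)
          d <- sum(vapply(cc, .mismatches, numeric(1), b = cons))
          if (d < best_d) {
            best_d <- d
            best <- cc
            best_lead <- lead
          }
        }
      }
      group_sites <- best
      lead <- best_lead
    }
    seqs <- c(seqs, group_sites)
    prov[[length(prov) + 1L]] <- data.frame(
      group_id = use$group_id[r], row = names(offs),
      offset = as.integer(offs) + lead, stringsAsFactors = FALSE)
  }
  site_set(tf_name, seqs, do.call(rbind, prov))
}

#' Write a region alignment as aligned FASTA
#'
#' @param alignment a `region_alignment`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(alignment$rows))
    writeLines(c(paste0(">", nm), alignment$rows[[nm]]), con)
}
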
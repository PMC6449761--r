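# PWM construction, scoring, palindrome symmetrization, consensus derivation,
# information content. Weights are natural-log odds versus a mononucleotide
# background; information content alone is reported in bits.

BASES <- c("A", "C", "G", "T")

.seq_to_idx <- function(s) {
  # A/C/G/T -> 1..4, N (or any other IUPAC code) -> NA; NA scores as background
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
}

.complement_idx <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G in BASES order

#' Build a site set
#'
#' A training set of aligned binding-site sequences of one transcription
#' factor, with optional provenance (genome, gene, position, strand).
#'
#' @param tf_name factor name.
#' @param sites character vector (>= 2) of equal-length A/C/G/T strings.
#' @param provenance optional data.frame with one row per site.
#' @return object of class `site_set`.
#' @export
site_set <- function(tf_name, sites, provenance = NULL) {
  sites <- toupper(sites)
  if (length(sites) < 2) stop("degenerate training set: need >= 2 sites")
  if (length(unique(nchar(sites))) != 1) stop("sites must all have equal length")
  if (any(grepl("[^ACGT]", sites))) stop("site alphabet is A/C/G/T only")
  if (!is.null(provenance)) stopifnot(nrow(provenance) == length(sites))
  structure(list(tf_name = tf_name, sites = sites, provenance = provenance),
            class = "site_set")
}

.freq_to_motif <- function(tf_name, freq, background, pseudocount,
                           palindromic, n_sites = NA_integer_) {
  weights <- log(freq / background)
  consensus <- .consensus_from_freq(freq)
  structure(list(tf_name = tf_name, length = ncol(freq), freq = freq,
                 weights = weights, background = background,
                 pseudocount = pseudocount, palindromic = palindromic,
                 consensus = consensus, n_sites = n_sites),
            class = "motif")
}

#' Build a position weight matrix from a site set
#'
#' Column frequencies are count-based with an additive pseudocount spread
#' according to the background: `f(b,j) = (count(b,j) + 4 p q_b) / (n + 4 p)`
#' where `p` is the pseudocount and `q` the background. Weights are
#' `ln(f(b,j) / q_b)`. The palindromic flag is auto-detected from the derived
#' consensus (self reverse-complement) unless given.
#'
#' @param sites a [site_set()] or character vector of equal-length sites.
#' @param pseudocount additive pseudocount (0 allowed).
#' @param background length-4 base frequencies (A,C,G,T); default uniform.
#'   Pass genome-wide mononucleotide frequencies for real scans
#'   (see [genome_background()]).
#' @param palindromic logical or NA (auto-detect).
#' @param tf_name used when `sites` is a bare character vector.
#' @return object of class `motif`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5,
                      background = rep(0.25, 4), palindromic = NA,
                      tf_name = "TF") {
  if (!inherits(sites, "site_set")) sites <- site_set(tf_name, sites)
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount >= 0)
  background <- stats::setNames(as.numeric(background), BASES)
  L <- nchar(sites$sites[1])
  n <- length(sites$sites)
  idx <- matrix(vapply(sites$sites, .seq_to_idx, integer(L)), nrow = L)
  counts <- matrix(0, 4, L, dimnames = list(BASES, NULL))
  for (j in seq_len(L)) {
    tb <- tabulate(idx[j, ], nbins = 4)
    counts[, j] <- tb
  }
  freq <- (counts + 4 * pseudocount * background) / (n + 4 * pseudocount)
  if (pseudocount == 0 && any(freq == 0)) {
    # keep log-odds finite: zero counts get a vanishing mass, not -Inf
    freq[freq == 0] <- 1e-12
  }
  m <- .freq_to_motif(sites$tf_name, freq, background, pseudocount,
                      palindromic = FALSE, n_sites = n)
  auto <- identical(revcomp(m$consensus), m$consensus)
  m$palindromic <- if (is.na(palindromic)) auto else isTRUE(palindromic)
  m
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s: length %d, consensus %s%s\n", x$tf_name, x$length,
              x$consensus, if (x$palindromic) " (palindromic)" else ""))
  invisible(x)
}

#' Score one window against a motif
#'
#' Sum over positions of the log-odds weight of the observed base. An N (or
#' other ambiguous) base contributes 0 (background ratio 1).
#'
#' @param motif a `motif`.
#' @param window nucleotide string of length `motif$length`.
#' @return scalar score (natural-log units).
#' @export
score_window <- function(motif, window) {
  v <- .seq_to_idx(window)
  if (length(v) != motif$length)
    stop("window length ", length(v), " != motif length ", motif$length)
  j <- which(!is.na(v))
  sum(motif$weights[cbind(v[j], j)])
}

# score every window of an integer-encoded sequence; NA bases contribute 0
.score_vector <- function(v, weights) {
  L <- ncol(weights)
  n <- length(v) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    w <- weights[, j][v[j:(j + n - 1L)]]
    w[is.na(w)] <- 0
    sc <- sc + w
  }
  sc
}

#' Maximum achievable score of a motif
#' @param motif a `motif`.
#' @return scalar: sum over columns of the maximum weight.
#' @export
max_score <- function(motif) sum(apply(motif$weights, 2, max))

#' Symmetrize a motif to an exact palindrome
#'
#' Averages each column with the complemented, mirrored column:
#' `f'(b,j) = (f(b,j) + f(comp(b), L-1-j)) / 2`, then recomputes weights and
#' consensus and sets the palindromic flag. Idempotent; palindromic motifs are
#' fixed points. Used before scanning for factors binding as homodimers.
#'
#' @param motif a `motif`.
#' @return symmetrized `motif`.
#' @export
symmetrize <- function(motif) {
  L <- motif$length
  f <- motif$freq
  mirror <- f[.complement_idx, L:1, drop = FALSE]
  rownames(mirror) <- BASES
  f2 <- (f + mirror) / 2
  m <- .freq_to_motif(motif$tf_name, f2, motif$background, motif$pseudocount,
                      palindromic = TRUE, n_sites = motif$n_sites)
  m
}

.consensus_from_freq <- function(freq, inclusion_threshold = 0.25) {
  codes <- apply(freq >= inclusion_threshold, 2, function(keep) {
    if (!any(keep) || all(keep)) return("n")
    set <- BASES[keep]
    hit <- names(Filter(function(s) setequal(s, set), IUPAC_SETS))
    code <- hit[1]
    if (length(set) == 1) toupper(code) else code
  })
  paste(codes, collapse = "")
}

#' Derive the IUPAC consensus of a motif
#'
#' Per column, the IUPAC code of the set of bases with frequency at or above
#' the inclusion threshold; columns where no base or all four bases qualify
#' give "n". Single bases are upper-case, degenerate codes lower-case,
#' following the convention used for printed motif consensi (e.g. the
#' AAATmTCGAkATTT palindrome).
#'
#' @param motif a `motif`.
#' @param inclusion_threshold minimum column frequency for a base to enter the
#'   consensus set; the default 0.25 reproduces two-letter codes (m, k) for
#'   balanced columns while excluding background-level noise.
#' @return IUPAC string.
#' @export
derive_consensus <- function(motif, inclusion_threshold = 0.25) {
  .consensus_from_freq(motif$freq, inclusion_threshold)
}

#' Per-column and total information content
#'
#' In bits, Kullback-Leibler form: `sum_b f log2(f / q_b)`, which reduces to
#' `2 + sum_b f log2 f` for a uniform background (the height of a logo
#' column).
#'
#' @param motif a `motif`.
#' @return list with `per_column` (numeric vector, bits) and `total` (bits).
#' @export
information_content <- function(motif) {
  per <- vapply(seq_len(motif$length), function(j) {
    f <- motif$freq[, j]
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / motif$background[nz]))
  }, numeric(1))
  list(per_column = per, total = sum(per))
}

#' Enumerate or sample exact instantiations of an IUPAC consensus
#'
#' Each degenerate position is resolved uniformly at random among its allowed
#' bases. Used to plant sites and to build reference motifs from a printed
#' consensus.
#'
#' @param consensus IUPAC string.
#' @param n number of instantiations.
#' @return character vector of length `n`.
#' @export
instantiate_consensus <- function(consensus, n = 1) {
  allowed <- .iupac_matrix(consensus)   # 4 x L logical
  L <- ncol(allowed)
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(L), function(j) {
      opts <- BASES[allowed[, j]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }, character(1))
}

#' Refine a seed motif against its training regions
#'
#' Footprint-harvested site seeds can be offset by a column or two when
#' chance conservation extends a window asymmetrically into the flanks. Each
#' refinement round rescans every training region with the current motif,
#' takes the single best-scoring window per region (either strand, in its
#' matching orientation), and rebuilds the PWM from those windows. This
#' re-registers the training set on a common frame; it is a re-anchoring of
#' footprint seeds, not de novo discovery.
#'
#' @param motif seed `motif`.
#' @param regions list of `upstream_region` objects (training genes'
#'   upstream windows).
#' @param iterations refinement rounds (default 2).
#' @param trim_ratio training windows scoring below `trim_ratio` times the
#'   median training-window score are treated as diverged copies and left
#'   out of the rebuilt matrix (they remain scannable targets; weak sites
#'   should be found by the scan, not absorbed into the model).
#' @return refined `motif`.
#' @export
refine_pwm <- function(motif, regions, iterations = 2, trim_ratio = 0.8) {
  for (it in seq_len(iterations)) {
    sites <- character(0)
    scores <- numeric(0)
    for (r in regions) {
      if (nchar(r$sequence) < motif$length) next
      hits <- scan_region(motif, r)
      top <- hits[1, ]
      i0 <- top$position + r$gene_start_offset   # 0-based window start
      win <- substr(r$sequence, i0 + 1, i0 + motif$length)
      if (top$strand == "-") win <- revcomp(win)
      sites <- c(sites, win)
      scores <- c(scores, top$score)
    }
    keep <- scores >= trim_ratio * stats::median(scores)
    if (sum(keep) >= 2) sites <- sites[keep]
    if (length(sites) < 2) return(motif)
    motif <- build_pwm(sites, pseudocount = motif$pseudocount,
                       background = motif$background,
                       tf_name = motif$tf_name)
  }
  motif
}

#' Genome-wide mononucleotide background frequencies
#'
#' @param genomes a [genome()] or list of genomes.
#' @return named length-4 frequency vector (A,C,G,T); N bases are ignored.
#' @export
genome_background <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  counts <- stats::setNames(numeric(4), BASES)
  for (gn in genomes) {
    for (ctg in gn$contigs) {
      tb <- table(strsplit(ctg, "", fixed = TRUE)[[1]])
      for (b in intersect(BASES, names(tb))) counts[b] <- counts[b] + tb[[b]]
    }
  }
  counts / sum(counts)
}

#' Write a motif in MEME minimal format
#'
#' @param motif a `motif`.
#' @param path output file.
#' @export
write_meme <- function(motif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               sprintf("Background letter frequencies"),
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       motif$background[1], motif$background[2],
                       motif$background[3], motif$background[4]), "",
               sprintf("MOTIF %s", motif$tf_name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                       motif$length,
                       ifelse(is.na(motif$n_sites), 20L, motif$n_sites))), con)
  writeLines(apply(motif$freq, 2, function(col)
    sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])), con)
}

#' Write a motif frequency matrix as TSV (position, A, C, G, T)
#'
#' The plain-matrix export consumable by any logo renderer.
#'
#' @param motif a `motif`.
#' @param path output file.
#' @export
write_pwm_tsv <- function(motif, path) {
  df <- data.frame(position = seq_len(motif$length), t(motif$freq))
  names(df) <- c("position", BASES)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
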
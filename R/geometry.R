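# Motif-geometry analyses: IUPAC palindrome verification, half-site spacer
# enumeration (e.g. TGCA-Nx-TGCA), LysR-family T-N11-A box detection, and
# helical-turn phasing of multi-site arrangements.

#' Verify an IUPAC consensus as a DNA palindrome
#'
#' A consensus is palindromic when it equals its IUPAC reverse complement.
#' For odd lengths the central position is exempt from the equality check
#' (any center symbol is allowed, self-complementary or not), matching the
#' convention of "odd palindromes" of LysR-family boxes.
#'
#' @param consensus IUPAC string.
#' @return list with `is_palindrome`, `length`, `parity` ("even"/"odd").
#' @export
check_palindrome <- function(consensus) {
  .check_iupac(consensus)
  L <- nchar(consensus)
  rc <- revcomp(consensus)
  if (L %% 2 == 0) {
    pal <- identical(toupper(rc), toupper(consensus))
  } else {
    mid <- (L + 1) %/% 2
    a <- toupper(consensus); b <- toupper(rc)
    substr(a, mid, mid) <- "N"
    substr(b, mid, mid) <- "N"
    pal <- identical(a, b)
  }
  list(is_palindrome = pal, length = L,
       parity = if (L %% 2 == 0) "even" else "odd")
}

.find_all <- function(seq, pattern) {
  # 0-based start offsets of exact (non-degenerate) matches, overlapping
  out <- integer(0)
  from <- 1L
  repeat {
    i <- regexpr(pattern, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (i < 0) break
    out <- c(out, from + i - 2L)
    from <- from + i
  }
  out
}

#' Enumerate half-site pairs and their spacers
#'
#' Counts every ordered pair of half-site occurrences whose gap (end of the
#' first occurrence to start of the second) lies in `spacer_range`. Pairs with
#' the second occurrence in direct-repeat orientation are tagged "direct";
#' pairs whose second occurrence matches the reverse complement of the
#' half-site are tagged "inverted" and counted separately. For
#' self-complementary half-sites such as TGCA the two orientations coincide
#' and only "direct" is reported. Pairs never span sequence boundaries.
#'
#' @param sequences character vector of A/C/G/T/N sequences.
#' @param half_site non-degenerate half-site (default "TGCA").
#' @param spacer_range integer vector of admissible gaps (default 0:20).
#' @return object of class `spacer_histogram`: list with `half_site`,
#'   `counts` (data.frame spacer/orientation/count) and `sources`
#'   (data.frame seq_index/offset1/offset2/spacer/orientation).
#' @export
enumerate_halfsite_spacers <- function(sequences, half_site = "TGCA",
                                       spacer_range = 0:20) {
  half_site <- toupper(half_site)
  if (grepl("[^ACGT]", half_site)) stop("half_site must be non-degenerate")
  rc <- revcomp(half_site)
  self_comp <- identical(rc, half_site)
  w <- nchar(half_site)
  src <- list()
  for (i in seq_along(sequences)) {
    s <- toupper(sequences[i])
    fwd <- .find_all(s, half_site)
    orients <- list(direct = fwd)
    if (!self_comp) orients$inverted <- .find_all(s, rc)
    for (orient in names(orients)) {
      second <- orients[[orient]]
      for (o1 in fwd) for (o2 in second) {
        gap <- o2 - (o1 + w)
        if (gap %in% spacer_range)
          src[[length(src) + 1L]] <- data.frame(
            seq_index = i, offset1 = o1, offset2 = o2, spacer = gap,
            orientation = orient, stringsAsFactors = FALSE)
      }
    }
  }
  sources <- if (length(src) > 0) do.call(rbind, src) else
    data.frame(seq_index = integer(0), offset1 = integer(0),
               offset2 = integer(0), spacer = integer(0),
               orientation = character(0), stringsAsFactors = FALSE)
  counts <- if (nrow(sources) > 0) {
    agg <- stats::aggregate(list(count = sources$seq_index),
                            by = list(spacer = sources$spacer,
                                      orientation = sources$orientation),
                            FUN = length)
    agg[order(agg$spacer, agg$orientation), , drop = FALSE]
  } else {
    data.frame(spacer = integer(0), orientation = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(counts) <- NULL
  structure(list(half_site = half_site, counts = counts, sources = sources),
            class = "spacer_histogram")
}

#' @export
print.spacer_histogram <- function(x, ...) {
  cat(sprintf("<spacer_histogram> half-site %s, %d pair(s)\n", x$half_site,
              nrow(x$sources)))
  if (nrow(x$counts) > 0) print(x$counts)
  invisible(x)
}

#' Spacer of the LysR-family T-Nx-A box in a consensus
#'
#' Finds the outermost symmetric position pair (i, L-1-i), with i minimal,
#' such that the IUPAC set at position i contains T and the set at position
#' L-1-i contains A, and returns the number of intervening positions,
#' `L - 2 - 2i`. On the canonical LysR box (an inverted repeat such as
#' AkACC-N5-GGTAT) this recovers the general T-N11-A motif spacer.
#'
#' @param consensus IUPAC string.
#' @return integer spacer (count of intervening positions).
#' @export
lysr_box_spacer <- function(consensus) {
  allowed <- .iupac_matrix(consensus)  # 4 x L
  L <- ncol(allowed)
  for (i in 0:(L %/% 2 - 1)) {
    if (allowed["T" == BASES, i + 1] && allowed["A" == BASES, L - i])
      return(L - 2L - 2L * as.integer(i))
  }
  stop("pattern not found: no symmetric position pair with T ... A")
}

#' Helical phasing of multiple binding sites
#'
#' Consecutive center-to-center distances and their nearest-integer counts of
#' DNA helical turns at `bp_per_turn`. Sites separated by a whole number of
#' turns face the same side of the helix, the arrangement expected for
#' cooperatively binding factors.
#'
#' @param site_centers numeric positions (nt), sorted ascending.
#' @param bp_per_turn helical repeat (default 10.5, B-DNA).
#' @return object of class `phasing_report`: list with `centers`, `distances`
#'   and `turns` (nearest integers).
#' @export
site_phasing <- function(site_centers, bp_per_turn = 10.5) {
  if (length(site_centers) < 2) stop("degenerate input: need >= 2 site centers")
  if (is.unsorted(site_centers)) stop("site centers must be sorted ascending")
  d <- diff(site_centers)
  structure(list(centers = site_centers, distances = d,
                 turns = as.integer(round(d / bp_per_turn)),
                 bp_per_turn = bp_per_turn),
            class = "phasing_report")
}

#' @export
print.phasing_report <- function(x, ...) {
  cat(sprintf("<phasing_report> %d sites; distances: %s; turns: %s (%.1f bp/turn)\n",
              length(x$centers), paste(x$distances, collapse = ", "),
              paste(x$turns, collapse = ", "), x$bp_per_turn))
  invisible(x)
}
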
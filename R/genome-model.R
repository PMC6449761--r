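# Genome / gene data model and upstream-window extraction.
# Coordinates are 0-based half-open internally; GenBank/GFF3 1-based inclusive
# coordinates are converted at the I/O boundary only.

IUPAC_SETS <- list(
  a = "A", c = "C", g = "G", t = "T",
  m = c("A", "C"), k = c("G", "T"), r = c("A", "G"), y = c("C", "T"),
  w = c("A", "T"), s = c("C", "G"),
  b = c("C", "G", "T"), d = c("A", "G", "T"), h = c("A", "C", "T"),
  v = c("A", "C", "G"), n = c("A", "C", "G", "T")
)

# complement map over the 15-letter IUPAC alphabet plus N, case preserved
.COMP_FROM <- "ACGTMKRYWSBDHVNacgtmkrywsbdhvn"
.COMP_TO   <- "TGCAKMYRWSVHDBNtgcakmyrwsvhdbn"

.check_iupac <- function(sequence) {
  bad <- gsub(sprintf("[%s]", .COMP_FROM), "", sequence)
  if (any(nchar(bad) > 0))
    stop("invalid alphabet: non-IUPAC character(s) '",
         paste(unique(unlist(strsplit(bad, ""))), collapse = ""), "'")
  invisible(TRUE)
}

#' Reverse complement under IUPAC complementation
#'
#' Complements all 15 IUPAC degeneracy codes plus N (m<->k, r<->y, w<->w,
#' s<->s, b<->v, d<->h, n<->n), preserving case, and reverses the sequence.
#' True DNA palindromes map to themselves.
#'
#' @param sequence character vector of nucleotide strings (IUPAC alphabet).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ATGC")
#' revcomp("AAATmTCGAkATTT")  # a palindrome maps to itself
#' @export
revcomp <- function(sequence) {
  .check_iupac(sequence)
  comp <- chartr(.COMP_FROM, .COMP_TO, sequence)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Scan-window and pipeline constants
#'
#' Bundles the tunable constants of the reconstruction procedure: the upstream
#' scan window (350 nt upstream, 50 nt downstream of the annotated gene start),
#' the calibration bound (at most 5\% of genes preceded by candidate sites per
#' genome), the weak-site rescue factor (sites scoring within 10\% of the
#' threshold), the operon intergenic-gap limit (200 nt), the number of genomes
#' required for cross-genome support, the positional tolerance for orthologous
#' site comparison, and the B-DNA helical repeat used for phasing.
#'
#' @param upstream_span nt upstream of the gene start included in the window.
#' @param downstream_span nt downstream of the gene start included.
#' @param max_hit_fraction maximum admissible fraction of genes with a
#'   candidate site per genome (threshold calibration bound).
#' @param rescue_factor sub-threshold sites down to `rescue_factor * threshold`
#'   are candidates for rescue.
#' @param operon_max_gap maximum intergenic distance (nt) inside an operon.
#' @param min_genomes genomes required to support a regulon member or an
#'   operon adjacency ("several genomes").
#' @param position_tolerance nt tolerance when comparing site positions
#'   upstream of orthologous genes.
#' @param bp_per_turn base pairs per DNA helical turn.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(upstream_span = 350L, downstream_span = 50L,
                        max_hit_fraction = 0.05, rescue_factor = 0.90,
                        operon_max_gap = 200L, min_genomes = 3L,
                        position_tolerance = 20L, bp_per_turn = 10.5) {
  stopifnot(upstream_span >= 0, downstream_span >= 0,
            max_hit_fraction > 0, max_hit_fraction <= 1,
            rescue_factor > 0, rescue_factor < 1,
            operon_max_gap >= 0, min_genomes >= 1, position_tolerance >= 0,
            bp_per_turn > 0)
  structure(list(upstream_span = as.integer(upstream_span),
                 downstream_span = as.integer(downstream_span),
                 max_hit_fraction = max_hit_fraction,
                 rescue_factor = rescue_factor,
                 operon_max_gap = as.integer(operon_max_gap),
                 min_genomes = as.integer(min_genomes),
                 position_tolerance = as.integer(position_tolerance),
                 bp_per_turn = bp_per_turn),
            class = "scan_config")
}

#' Construct a genome object
#'
#' A genome is a set of named contig sequences plus a gene table with 0-based
#' half-open coordinates. Genes are re-sorted by (contig_id, start) and
#' validated against the contigs.
#'
#' @param genome_id identifier.
#' @param contigs named character vector (or `DNAStringSet`) of contig
#'   sequences over A/C/G/T/N.
#' @param genes data.frame with columns gene_id, contig_id, start, end, strand
#'   and optionally locus_tag, product.
#' @return object of class `genome`.
#' @export
genome <- function(genome_id, contigs, genes) {
  if (inherits(contigs, "DNAStringSet")) contigs <- as.character(contigs)
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (is.null(genes$locus_tag)) genes$locus_tag <- genes$gene_id
  if (is.null(genes$product)) genes$product <- ""
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("gene_id values must be unique within a genome")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene intervals require start < end")
  if (!all(genes$contig_id %in% names(contigs)))
    stop("gene contig_id not found among contigs")
  clen <- nchar(contigs)[genes$contig_id]
  if (any(genes$start < 0) || any(genes$end > clen))
    stop("gene interval outside its contig")
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d contig(s), %d genes, %d bp\n", x$genome_id,
              length(x$contigs), nrow(x$genes), sum(nchar(x$contigs))))
  invisible(x)
}

.gene_row <- function(gn, gene_id) {
  i <- match(gene_id, gn$genes$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' not found in genome ", gn$genome_id)
  gn$genes[i, , drop = FALSE]
}

#' Extract the upstream scan window of a gene
#'
#' Returns the region spanning `upstream_span` nt upstream and
#' `downstream_span` nt downstream of the annotated gene start, oriented 5'->3'
#' relative to the gene (minus-strand regions are reverse-complemented).
#' Windows are clipped at contig edges, never rejected; `gene_start_offset`
#' gives the index (0-based) of the annotated start inside the oriented
#' sequence and equals `upstream_span` unless the upstream side was truncated.
#'
#' @param gn a [genome()].
#' @param gene_id gene identifier.
#' @param config a [scan_config()].
#' @return list of class `upstream_region` with fields gene_id, contig_id,
#'   interval (0-based half-open, contig coordinates), strand, sequence,
#'   gene_start_offset.
#' @export
extract_upstream <- function(gn, gene_id, config = scan_config()) {
  g <- .gene_row(gn, gene_id)
  clen <- nchar(gn$contigs[[g$contig_id]])
  if (g$strand == "+") {
    lo <- max(0L, g$start - config$upstream_span)
    hi <- min(clen, g$start + config$downstream_span)
    seq <- substr(gn$contigs[[g$contig_id]], lo + 1L, hi)
    offset <- g$start - lo
  } else {
    lo <- max(0L, g$end - config$downstream_span)
    hi <- min(clen, g$end + config$upstream_span)
    seq <- revcomp(substr(gn$contigs[[g$contig_id]], lo + 1L, hi))
    offset <- hi - g$end
  }
  structure(list(gene_id = g$gene_id, contig_id = g$contig_id,
                 interval = c(lo, hi), strand = g$strand, sequence = seq,
                 gene_start_offset = as.integer(offset)),
            class = "upstream_region")
}

#' Upstream windows for all (or selected) genes of a genome
#'
#' @inheritParams extract_upstream
#' @param gene_ids genes to extract; default all.
#' @return named list of `upstream_region` objects.
#' @export
upstream_regions <- function(gn, gene_ids = gn$genes$gene_id,
                             config = scan_config()) {
  out <- lapply(gene_ids, extract_upstream, gn = gn, config = config)
  names(out) <- gene_ids
  out
}

# expand an IUPAC consensus into the matrix of allowed-base indicator columns
.iupac_matrix <- function(consensus) {
  chars <- strsplit(tolower(consensus), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) stop("invalid alphabet: '", paste(bad, collapse = ""), "'")
  vapply(chars, function(ch) c("A", "C", "G", "T") %in% IUPAC_SETS[[ch]],
         logical(4))
}
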
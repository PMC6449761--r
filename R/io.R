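# Readers and writers for the standard formats: GFF3 + FASTA (rtracklayer /
# Biostrings), a minimal GenBank flat-file reader/writer, gene and ortholog
# tables as TSV, hits as TSV and BED6. All exported interval files use BED
# conventions (0-based half-open); GenBank/GFF3 1-based inclusive coordinates
# are converted at this boundary.

#' Read a genome from a GFF3 + FASTA pair
#'
#' CDS (or gene, if no CDS present) features become genes; `gene_id` is taken
#' from the locus_tag attribute, falling back to ID.
#'
#' @param gff_path GFF3 file.
#' @param fasta_path FASTA file with the contig sequences.
#' @param genome_id identifier; default the GFF file stem.
#' @return a [genome()].
#' @export
read_genome_gff <- function(gff_path, fasta_path,
                            genome_id = sub("\\.gff3?$", "",
                                            basename(gff_path))) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff_path)
  type <- as.character(gr$type)
  gr <- gr[type %in% if ("CDS" %in% type) "CDS" else "gene"]
  ids <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else
    as.character(gr$ID)
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = ids,
    product = if (!is.null(gr$product)) as.character(gr$product) else "",
    stringsAsFactors = FALSE)
  genome(genome_id, as.character(contigs), genes)
}

#' Write a genome as a GFF3 + FASTA pair
#'
#' @param gn a [genome()].
#' @param gff_path,fasta_path output files.
#' @export
write_genome_gff <- function(gn, gff_path, fasta_path) {
  seqs <- Biostrings::DNAStringSet(gn$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path)
  g <- gn$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- "CDS"
  gr$source <- "regulonscan"
  gr$phase <- 0L
  gr$ID <- g$gene_id
  gr$locus_tag <- g$locus_tag
  gr$product <- g$product
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(gff = gff_path, fasta = fasta_path))
}

# ---- minimal GenBank flat file support -------------------------------------
# Single- or multi-record files with LOCUS / FEATURES (CDS) / ORIGIN blocks.
# Compound join() locations are reduced to their outermost span with a
# warning; complement() sets the strand.

.parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  if (grepl("join|order", loc))
    warning("compound location reduced to outermost span: ", loc)
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  c(start = min(nums) - 1L, end = max(nums), strand = strand)
}

#' Read a genome from a GenBank flat file
#'
#' Minimal parser covering LOCUS, FEATURES (CDS features with locus_tag and
#' product qualifiers) and ORIGIN sequence blocks. Compound (join) locations
#' are reduced to the outermost span with a warning.
#'
#' @param path GenBank flat file.
#' @param genome_id identifier; default the file stem.
#' @return a [genome()].
#' @export
read_genbank <- function(path, genome_id = sub("\\.(gb|gbk|gbff)$", "",
                                               basename(path))) {
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) stop("no LOCUS record in ", path)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  contigs <- character(0)
  genes <- list()
  for (ri in seq_along(rec_starts)) {
    rec <- lines[rec_starts[ri]:rec_ends[ri]]
    contig_id <- strsplit(trimws(sub("^LOCUS\\s+", "", rec[1])), "\\s+")[[1]][1]
    oi <- grep("^ORIGIN", rec)[1]
    seq_lines <- rec[(oi + 1):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seq
    fi <- grep("^FEATURES", rec)[1]
    if (!is.na(fi)) {
      feat <- rec[(fi + 1):(oi - 1)]
      is_key <- grepl("^ {5}\\S", feat)
      key_idx <- which(is_key)
      for (ki in seq_along(key_idx)) {
        line <- feat[key_idx[ki]]
        key <- trimws(substr(line, 1, 21))
        if (key != "CDS") next
        block_end <- if (ki < length(key_idx)) key_idx[ki + 1] - 1L else
          length(feat)
        block <- feat[key_idx[ki]:block_end]
        loc <- trimws(substr(block[1], 22, nchar(block[1])))
        qi <- grep("^\\s+/", block)
        quals <- block[qi]
        # continuation lines of the location live before the first qualifier
        if (length(qi) > 0 && qi[1] > 2)
          loc <- paste0(loc, paste(trimws(block[2:(qi[1] - 1)]),
                                   collapse = ""))
        getq <- function(name) {
          m <- grep(sprintf('^\\s+/%s="?', name), quals, value = TRUE)
          if (length(m) == 0) return(NA_character_)
          gsub(sprintf('^\\s+/%s="?|"$', name), "", m[1])
        }
        pl <- .parse_gb_location(loc)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = NA_character_, contig_id = contig_id,
          start = as.integer(pl["start"]), end = as.integer(pl["end"]),
          strand = unname(pl["strand"]),
          locus_tag = getq("locus_tag"), product = getq("product"),
          stringsAsFactors = FALSE)
      }
    }
  }
  genes <- do.call(rbind, genes)
  if (is.null(genes)) stop("no CDS features in ", path)
  genes$gene_id <- ifelse(is.na(genes$locus_tag),
                          sprintf("cds%04d", seq_len(nrow(genes))),
                          genes$locus_tag)
  genes$locus_tag <- genes$gene_id
  genes$product[is.na(genes$product)] <- ""
  genome(genome_id, contigs, genes)
}

#' Write a genome as a GenBank flat file
#'
#' @param gn a [genome()].
#' @param path output file.
#' @export
write_genbank <- function(gn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(gn$contigs)) {
    seq <- gn$contigs[[ctg]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", ctg,
                       nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s synthetic sequence.", gn$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- gn$genes[gn$genes$contig_id == ctg, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"',
                         g$locus_tag[i]), con)
      if (nzchar(g$product[i]))
        writeLines(sprintf('                     /product="%s"',
                           g$product[i]), con)
    }
    writeLines("ORIGIN", con)
    starts <- seq(1, nchar(seq), by = 60)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59, nchar(seq)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write the gene table of a genome as TSV (BED-convention coordinates)
#'
#' @param gn a [genome()].
#' @param path output file.
#' @export
write_gene_table <- function(gn, path) {
  df <- data.frame(genome_id = gn$genome_id, contig_id = gn$genes$contig_id,
                   gene_id = gn$genes$gene_id, start = gn$genes$start,
                   end = gn$genes$end, strand = gn$genes$strand,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an ortholog-group table (TSV: group_id, genome_id, gene_id)
#'
#' @param path TSV file.
#' @return data.frame with columns group_id, genome_id, gene_id.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("group_id", "genome_id", "gene_id") %in% names(df)))
  df
}

#' @rdname read_ortholog_table
#' @param ortholog_table data.frame to write.
#' @export
write_ortholog_table <- function(ortholog_table, path) {
  utils::write.table(ortholog_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export site hits as BED6 for one genome
#'
#' Scores are the threshold ratio scaled to 0-1000 (clamped).
#'
#' @param hits hit table ([scan_hits()] / [final_hits()]).
#' @param gn the [genome()] the hits refer to.
#' @param site_width motif length (nt).
#' @param path output BED file.
#' @export
write_hits_bed <- function(hits, gn, site_width, path) {
  h <- hits[hits$genome_id == gn$genome_id, , drop = FALSE]
  if (nrow(h) > 0) {
    iv <- t(vapply(seq_len(nrow(h)), function(i) {
      g <- .gene_row(gn, h$gene_id[i])
      .hit_contig_interval(g, h$position[i], site_width)
    }, numeric(2)))
    ctg <- vapply(h$gene_id, function(id) .gene_row(gn, id)$contig_id,
                  character(1))
    bed <- data.frame(chrom = ctg, start = as.integer(iv[, 1]),
                      end = as.integer(iv[, 2]), name = h$tf_name,
                      score = pmin(1000L, pmax(0L,
                        as.integer(round(1000 * h$score_ratio)))),
                      strand = h$strand, stringsAsFactors = FALSE)
  } else {
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits each genome as GFF3 + FASTA (or GenBank), the ortholog table and
#' ground truth as TSV, and a YAML run manifest recording the seed and all
#' paths.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param dir output directory (created).
#' @param format "gff3" or "genbank".
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("gff3", "genbank")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (gn in dataset$genomes) {
    if (format == "gff3") {
      p <- write_genome_gff(gn, file.path(dir, paste0(gn$genome_id, ".gff3")),
                            file.path(dir, paste0(gn$genome_id, ".fasta")))
      paths[[gn$genome_id]] <- as.list(p)
    } else {
      paths[[gn$genome_id]] <- write_genbank(
        gn, file.path(dir, paste0(gn$genome_id, ".gb")))
    }
  }
  ortho_path <- file.path(dir, "orthologs.tsv")
  write_ortholog_table(dataset$ortholog_table, ortho_path)
  truth_path <- file.path(dir, "truth_sites.tsv")
  utils::write.table(dataset$truth$planted_sites, truth_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(seed = dataset$seed, format = format,
                   genomes = paths, orthologs = ortho_path,
                   truth_sites = truth_path,
                   membership = dataset$truth$regulon_membership)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
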
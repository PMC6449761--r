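# Independent oracles and small fixture builders used across the suite.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# Affine-gap global alignment optimum (match +1 / mismatch -1 / a gap of
# length L costs open + L*ext), computed by an independent three-state DP --
# equals the optimum over exhaustive enumeration of alignments.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 3, gap_ext = 1) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ia <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Ib <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i > 0 && j > 0)
      M[i + 1, j + 1] <- max(M[i, j], Ia[i, j], Ib[i, j]) +
        if (av[i] == bv[j]) match else mismatch
    if (i > 0)
      Ia[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ia[i, j + 1] - gap_ext)
    if (j > 0)
      Ib[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Ib[i + 1, j] - gap_ext)
  }
  max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
}

# Plain per-position table-lookup summation, independent of the vectorized
# scanning path.
oracle_score <- function(motif, window) {
  chars <- strsplit(toupper(window), "")[[1]]
  total <- 0
  for (j in seq_along(chars)) {
    b <- match(chars[j], BASES4)
    if (!is.na(b)) total <- total + unname(motif$weights[b, j])
  }
  total
}

# Score of one pairwise alignment extracted from a star alignment (gap of
# length L costs open + L*ext), for checking alignment optimality.
aligned_pair_score <- function(row_a, row_b, match = 1, mismatch = -1,
                               gap_open = 3, gap_ext = 1) {
  a <- strsplit(row_a, "")[[1]]; b <- strsplit(row_b, "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  sc <- 0
  in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      sc <- sc - gap_ext - if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      sc <- sc + if (a[k] == b[k]) match else mismatch
      in_gap <- FALSE
    }
  }
  sc
}

# A small hand-laid genome: one 5000 nt contig with genes at known
# coordinates (plus-strand at 1000, edge gene at 10, minus-strand ending at
# 2000).
toy_genome <- function(seed = 42) {
  set.seed(seed)
  contig <- rand_dna(5000)
  genes <- data.frame(
    gene_id = c("edge", "plus", "minus"),
    contig_id = "c1",
    start = c(10L, 1000L, 1500L),
    end = c(400L, 1400L, 2000L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  genome("toy", c(c1 = contig), genes)
}

# Genome of one contig with + genes of width 100 whose intergenic gaps are
# given; used for operon rule-boundary checks.
gap_genome <- function(gaps, strands = NULL, genome_id = "gapg") {
  n <- length(gaps) + 1
  if (is.null(strands)) strands <- rep("+", n)
  starts <- integer(n); starts[1] <- 500L
  for (i in seq_along(gaps)) starts[i + 1] <- starts[i] + 100L + gaps[i]
  set.seed(7)
  contig <- rand_dna(starts[n] + 100L + 500L)
  genes <- data.frame(gene_id = paste0("g", seq_len(n)), contig_id = "c1",
                      start = starts, end = starts + 100L, strand = strands,
                      stringsAsFactors = FALSE)
  genome(genome_id, c(c1 = contig), genes)
}

aphs_consensus <- "AAATmTCGAkATTT"

# The standard benchmark dataset of the suite (5 genomes x 200 genes, six
# planted target operon leaders).
bench_dataset <- function(seed, weak_fraction = 0, n_genomes = 5,
                          n_groups = 200, n_targets = 6) {
  generate_dataset(
    n_genomes = n_genomes, n_groups = n_groups,
    plants = plant_spec("AphS", aphs_consensus, n_targets,
                        weak_fraction = weak_fraction),
    seed = seed)
}

run_bench_pipeline <- function(ds, out_dir) {
  pc <- pipeline_config(
    ds$genomes, ds$ortholog_table,
    tfs = list(list(name = "AphS",
                    training_groups = ds$truth$regulon_membership$AphS,
                    palindromic = TRUE)),
    out_dir = out_dir)
  run_pipeline(pc)
}
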
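test_that("operons merge under 200 nt gaps and split over them or at strand flips", {
  ops <- infer_operons(gap_genome(c(150, 150)))
  expect_identical(nrow(ops), 1L)
  expect_identical(ops$genes[[1]], c("g1", "g2", "g3"))
  expect_identical(ops$leader, "g1")

  ops2 <- infer_operons(gap_genome(c(150, 250)))
  expect_identical(ops2$n_genes, c(2L, 1L))

  ops3 <- infer_operons(gap_genome(c(50, 50), strands = c("+", "+", "-")))
  expect_identical(lapply(ops3$genes, identity),
                   list(c("g1", "g2"), "g3"))
  # the minus-strand singleton is its own leader
  expect_identical(ops3$leader, c("g1", "g3"))
})

test_that("minus-strand operons are reported in transcription order", {
  ops <- infer_operons(gap_genome(c(100, 100), strands = rep("-", 3)))
  expect_identical(nrow(ops), 1L)
  expect_identical(ops$genes[[1]], c("g3", "g2", "g1"))
  expect_identical(ops$leader, "g3")
})

test_that("operon partition covers every gene exactly once, with limit behavior", {
  set.seed(71)
  ds <- generate_dataset(n_genomes = 2, n_groups = 50, seed = 29)
  gn <- ds$genomes[[1]]
  ops <- infer_operons(gn)
  all_genes <- sort(unlist(ops$genes))
  expect_identical(all_genes, sort(gn$genes$gene_id))
  # gap limit 0: singletons unless genes abut exactly
  ops0 <- infer_operons(gn, scan_config(operon_max_gap = 0))
  expect_true(all(ops0$n_genes == 1))
  # effectively unbounded gap: maximal same-strand runs
  opsInf <- infer_operons(gn, scan_config(operon_max_gap = 10^9))
  rl <- rle(gn$genes$strand)
  expect_identical(opsInf$n_genes, rl$lengths)
})

persistence_fixture <- function() {
  # five genomes; groups A-B adjacent in three, B-C in one; genome G4 has an
  # unmapped insert between A and B
  mk <- function(gid, genes) {
    g <- gap_genome(rep(50, length(genes) - 1), genome_id = gid)
    g$genes$gene_id <- genes
    g$genes$locus_tag <- genes
    infer_operons(genome(gid, g$contigs, g$genes))
  }
  o <- list(
    G1 = mk("G1", c("G1_a", "G1_b")),
    G2 = mk("G2", c("G2_a", "G2_b")),
    G3 = mk("G3", c("G3_a", "G3_b", "G3_c")),
    G4 = mk("G4", c("G4_a", "G4_x", "G4_b")),
    G5 = mk("G5", c("G5_q", "G5_r"))
  )
  ortho <- data.frame(
    group_id = c("A", "B", "A", "B", "A", "B", "C", "A", "B", "Q", "R"),
    genome_id = c("G1", "G1", "G2", "G2", "G3", "G3", "G3", "G4", "G4",
                  "G5", "G5"),
    gene_id = c("G1_a", "G1_b", "G2_a", "G2_b", "G3_a", "G3_b", "G3_c",
                "G4_a", "G4_b", "G5_q", "G5_r"),
    stringsAsFactors = FALSE)
  list(operons = o, ortho = ortho)
}

test_that("operon adjacencies persist across genomes, skipping unmapped inserts", {
  fx <- persistence_fixture()
  pers <- check_operon_persistence(fx$operons, fx$ortho, min_genomes = 2)
  ab <- pers[pers$group_a == "A" & pers$group_b == "B", ]
  # A-B adjacency: G1, G2, G3 directly, plus G4 across its unmapped insert
  expect_identical(ab$n_genomes, 4L)
  expect_true(ab$supported)
  bc <- pers[pers$group_a == "B" & pers$group_b == "C", ]
  expect_identical(bc$n_genomes, 1L)
  expect_false(bc$supported)
  # stricter support requirement is honored
  pers5 <- check_operon_persistence(fx$operons, fx$ortho, min_genomes = 5)
  expect_false(any(pers5$supported))
})

regulon_fixture <- function(n_support = 3) {
  genomes <- paste0("G", 1:5)
  ortho <- do.call(rbind, lapply(genomes, function(g)
    data.frame(group_id = c("A", "B", "C"), genome_id = g,
               gene_id = paste0(g, "_", c("a", "b", "c")),
               stringsAsFactors = FALSE)))
  operons <- lapply(genomes, function(g) {
    gn <- gap_genome(c(400, 150), genome_id = g)
    gn$genes$gene_id <- paste0(g, "_", c("a", "b", "c"))
    infer_operons(genome(g, gn$contigs, gn$genes))
  })
  # operon structure per genome: {a} and {b, c}; group A hits in n_support
  # genomes, group B (leader of b-c) hit in exactly one
  hits <- data.frame(
    tf_name = "TF",
    genome_id = c(genomes[seq_len(n_support)], "G1"),
    gene_id = c(paste0(genomes[seq_len(n_support)], "_a"), "G1_b"),
    position = -120L, strand = "+", score = 12,
    score_ratio = 1.2, category = "strong",
    rescue_clause = NA_character_, stringsAsFactors = FALSE)
  list(ortho = ortho, operons = operons, hits = hits)
}

test_that("regulon membership needs several genomes; singletons go to a side table", {
  fx <- regulon_fixture(n_support = 3)
  reg <- assemble_regulon("TF", fx$hits, fx$ortho, fx$operons)
  expect_identical(reg$core$group_id, "A")
  expect_identical(reg$core$n_support_genomes, 3L)
  # group B had evidence in one genome only
  expect_true("B" %in% reg$singletons$group_id)
  expect_false("B" %in% reg$core$group_id)
})

test_that("membership is monotone in the support requirement and order-invariant", {
  fx <- regulon_fixture(n_support = 3)
  sizes <- vapply(1:5, function(mg) {
    nrow(assemble_regulon("TF", fx$hits, fx$ortho, fx$operons,
                          scan_config(min_genomes = mg))$core)
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  reg_fwd <- assemble_regulon("TF", fx$hits, fx$ortho, fx$operons)
  reg_rev <- assemble_regulon("TF", fx$hits, fx$ortho, rev(fx$operons))
  expect_identical(reg_fwd$core, reg_rev$core)
})

test_that("regulons extend through operons but stop at unsupported adjacencies", {
  fx <- regulon_fixture(n_support = 3)
  # move the hits onto the leaders of the two-gene operon {b, c}
  fx$hits <- data.frame(
    tf_name = "TF", genome_id = paste0("G", 1:3),
    gene_id = paste0("G", 1:3, "_b"), position = -120L, strand = "+",
    score = 12, score_ratio = 1.2, category = "strong",
    rescue_clause = NA_character_, stringsAsFactors = FALSE)
  reg <- assemble_regulon("TF", fx$hits, fx$ortho, fx$operons)
  expect_identical(reg$core$group_id, "B")
  mem <- reg$members[reg$members$genome_id == "G1", ]
  # b is core, c is reached by extension (B-C adjacency present in all five)
  expect_identical(mem$role[mem$gene_id == "G1_b"], "core")
  expect_identical(mem$role[mem$gene_id == "G1_c"], "extended")
  # break persistence: keep the b-c adjacency in one genome only
  ortho2 <- fx$ortho
  ortho2$group_id[ortho2$gene_id %in%
                    paste0("G", 2:5, "_c")] <- paste0("C", 2:5)
  reg2 <- assemble_regulon("TF", fx$hits, ortho2, fx$operons)
  mem2 <- reg2$members[reg2$members$genome_id == "G1", ]
  expect_false("G1_c" %in% mem2$gene_id)
})

test_that("internal-gene hits become candidate transcription units, not core evidence", {
  fx <- regulon_fixture(n_support = 3)
  # hits on the internal gene c of the {b, c} operon in three genomes
  fx$hits <- data.frame(
    tf_name = "TF", genome_id = paste0("G", 1:3),
    gene_id = paste0("G", 1:3, "_c"), position = -60L, strand = "+",
    score = 12, score_ratio = 1.2, category = "strong",
    rescue_clause = NA_character_, stringsAsFactors = FALSE)
  reg <- assemble_regulon("TF", fx$hits, fx$ortho, fx$operons)
  expect_identical(nrow(reg$core), 0L)
  expect_identical(sort(unique(reg$internal_tu$gene_id)),
                   paste0("G", 1:3, "_c"))
})

test_that("divergons share hits only inside the window overlap", {
  set.seed(73)
  contig <- rand_dna(4000)
  mk <- function(b_start) {
    genes <- data.frame(
      gene_id = c("A", "B"), contig_id = "c1",
      start = c(200L, b_start), end = c(800L, b_start + 600L),
      strand = c("-", "+"), stringsAsFactors = FALSE)
    genome("dv", c(c1 = contig), genes)
  }
  close_gn <- mk(1100L)   # heads 300 nt apart: windows overlap fully
  d <- detect_divergons(close_gn)
  expect_identical(nrow(d), 1L)
  expect_identical(c(d$gene_a, d$gene_b), c("A", "B"))

  # one physical site at contig 943 seen from both genes (position -157 in
  # each gene's own frame) is reported once as shared
  hits <- data.frame(tf_name = "TF", genome_id = "dv",
                     gene_id = c("A", "B"),
                     position = c(-157L, -157L), strand = "+",
                     score = 10, score_ratio = 1.1, category = "strong",
                     stringsAsFactors = FALSE)
  d2 <- detect_divergons(close_gn, hits, site_width = 14)
  expect_identical(d2$n_shared_hits, 1L)

  # 900 nt apart: the windows no longer overlap, so nothing is shared and a
  # hit near gene A stays attributed to A alone
  far_gn <- mk(1700L)
  expect_identical(nrow(detect_divergons(far_gn)), 0L)

  # tail-to-tail pairs are not divergons
  tt <- genome("tt", c(c1 = contig),
               data.frame(gene_id = c("A", "B"), contig_id = "c1",
                          start = c(200L, 1100L), end = c(800L, 1700L),
                          strand = c("+", "-"), stringsAsFactors = FALSE))
  expect_identical(nrow(detect_divergons(tt)), 0L)
})
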
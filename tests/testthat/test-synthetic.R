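test_that("generation is byte-identical for a fixed seed", {
  ds1 <- generate_dataset(n_genomes = 3, n_groups = 30,
                          plants = plant_spec("AphS", aphs_consensus, 3,
                                              weak_fraction = 0.2),
                          seed = 4)
  ds2 <- generate_dataset(n_genomes = 3, n_groups = 30,
                          plants = plant_spec("AphS", aphs_consensus, 3,
                                              weak_fraction = 0.2),
                          seed = 4)
  for (g in names(ds1$genomes)) {
    expect_identical(ds1$genomes[[g]]$contigs, ds2$genomes[[g]]$contigs)
    expect_identical(ds1$genomes[[g]]$genes, ds2$genomes[[g]]$genes)
  }
  expect_identical(ds1$truth$planted_sites, ds2$truth$planted_sites)
  ds3 <- generate_dataset(n_genomes = 3, n_groups = 30,
                          plants = plant_spec("AphS", aphs_consensus, 3),
                          seed = 5)
  expect_false(identical(ds1$genomes[["G1"]]$contigs,
                         ds3$genomes[["G1"]]$contigs))
})

test_that("planted sites sit inside upstream windows and realize the truth table", {
  ds <- generate_dataset(n_genomes = 4, n_groups = 40,
                         plants = plant_spec("AphS", aphs_consensus, 4),
                         seed = 6)
  ts <- ds$truth$planted_sites
  cfg <- scan_config()
  expect_true(all(ts$position >= -cfg$upstream_span))
  expect_true(all(ts$position + nchar(ts$instantiation) <=
                    cfg$downstream_span))
  # the recorded sequence is really present in the upstream region
  for (i in seq_len(nrow(ts))) {
    r <- extract_upstream(ds$genomes[[ts$genome_id[i]]], ts$gene_id[i], cfg)
    p0 <- ts$position[i] + r$gene_start_offset
    found <- substr(r$sequence, p0 + 1, p0 + nchar(ts$instantiation))
    oriented <- if (ts$strand[i] == "+") ts$sequence[i] else
      revcomp(ts$sequence[i])
    expect_identical(found, oriented)
  }
  # every member group carries sites in at least min_genomes genomes
  sup <- table(unique(ts[, c("group_id", "genome_id")])$group_id)
  expect_true(all(sup >= cfg$min_genomes))
})

test_that("with weak_fraction zero every planted site is an exact instantiation", {
  ds <- generate_dataset(n_genomes = 3, n_groups = 40,
                         plants = plant_spec("AphS", aphs_consensus, 4),
                         seed = 7)
  ts <- ds$truth$planted_sites
  expect_true(all(ts$category == "strong"))
  expect_identical(ts$sequence, ts$instantiation)
  # scanning each target region recovers the site at its planted position
  motif <- ds$generator$AphS$motif
  for (i in seq_len(nrow(ts))) {
    r <- extract_upstream(ds$genomes[[ts$genome_id[i]]], ts$gene_id[i])
    hits <- scan_region(motif, r)
    expect_identical(hits$position[1], ts$position[i])
  }
})

test_that("weakened sites land in the rescue band under the calibrated threshold", {
  ds <- generate_dataset(n_genomes = 5, n_groups = 100,
                         plants = plant_spec("AphS", aphs_consensus, 5,
                                             weak_fraction = 0.2),
                         seed = 8)
  ts <- ds$truth$planted_sites
  weak <- ts[ts$category == "weak", ]
  expect_gt(nrow(weak), 0)
  motif <- ds$generator$AphS$motif
  t <- ds$generator$AphS$threshold
  cfg <- scan_config()
  for (i in seq_len(nrow(weak))) {
    sc <- score_window(motif, weak$sequence[i])
    expect_gte(sc, cfg$rescue_factor * t)
    expect_lt(sc, t)
  }
  # no target group is left without at least min_genomes strong copies
  strong_sup <- table(ts$group_id[ts$category == "strong"])
  expect_true(all(strong_sup >= cfg$min_genomes))
})

test_that("operon layout respects the gap rules it advertises", {
  ds <- generate_dataset(n_genomes = 2, n_groups = 60, seed = 9)
  gn <- ds$genomes[[1]]
  ops <- infer_operons(gn)
  truth_runs <- ds$truth$operon_layout[[gn$genome_id]]
  expect_identical(lapply(ops$genes, identity), truth_runs)
})

test_that("an infeasible plant is rejected before any work is done", {
  expect_error(
    generate_dataset(n_genomes = 2, n_groups = 10,
                     plants = plant_spec("X", aphs_consensus, 2,
                                         site_position_range = c(-600, -500)),
                     seed = 1),
    "infeasible plant")
  expect_error(plant_spec("X", "", 1))
})

divergent_genome <- function(b_start = 1100L, contig_len = 4000L) {
  set.seed(79)
  genes <- data.frame(
    gene_id = c("A", "B"), contig_id = "c1",
    start = c(200L, b_start), end = c(800L, b_start + 600L),
    strand = c("-", "+"), stringsAsFactors = FALSE)
  genome("dv", c(c1 = rand_dna(contig_len)), genes)
}

test_that("divergon planting places one site inside both upstream windows", {
  gn <- divergent_genome(1100L)   # heads 300 nt apart
  set.seed(81)
  out <- plant_divergon(gn, "A", "B", aphs_consensus)
  expect_true(out$site$in_window_a)
  expect_true(out$site$in_window_b)
  # the planted sequence is really on the contig
  expect_identical(substr(out$genome$contigs[["c1"]],
                          out$site$contig_start + 1, out$site$contig_end),
                   out$site$sequence)
  # and both genes' oriented windows contain it
  ra <- extract_upstream(out$genome, "A")
  pa <- out$site$position_a + ra$gene_start_offset
  expect_identical(substr(ra$sequence, pa + 1, pa + 14),
                   revcomp(out$site$sequence))
})

test_that("divergon sites far from one partner stay outside its window", {
  gn <- divergent_genome(1700L)   # 900 nt intergenic span
  set.seed(83)
  # site 50 nt upstream of gene A's start (gene A is the minus-strand gene)
  out <- plant_divergon(gn, "A", "B", aphs_consensus, position = -64L)
  expect_true(out$site$in_window_a)
  expect_false(out$site$in_window_b)
})

test_that("non-divergent pairs are layout errors", {
  set.seed(85)
  same <- genome("ss", c(c1 = rand_dna(3000)),
                 data.frame(gene_id = c("A", "B"), contig_id = "c1",
                            start = c(200L, 1100L), end = c(800L, 1700L),
                            strand = c("+", "+"), stringsAsFactors = FALSE))
  expect_error(plant_divergon(same, "A", "B", aphs_consensus),
               "layout error")
  tailtail <- genome("tt", c(c1 = rand_dna(3000)),
                     data.frame(gene_id = c("A", "B"), contig_id = "c1",
                                start = c(200L, 1100L), end = c(800L, 1700L),
                                strand = c("+", "-"),
                                stringsAsFactors = FALSE))
  expect_error(plant_divergon(tailtail, "A", "B", aphs_consensus),
               "layout error")
})
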
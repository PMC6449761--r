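# End-to-end pipeline: footprint -> build PWM -> calibrate -> scan -> rescue
# -> operons -> regulon -> geometry, with stage outputs, an audit log and a
# checksummed run manifest. Re-running with identical inputs reproduces
# byte-identical outputs.

#' Build a validated pipeline configuration
#'
#' Inputs may be in-memory objects (a list of [genome()]s and an ortholog
#' data.frame, e.g. straight from [generate_dataset()]) or file paths
#' (GFF3+FASTA pairs / GenBank files and a TSV ortholog table). Each factor
#' is defined by its training ortholog groups, whose orthologous upstream
#' regions seed the footprinting stage.
#'
#' @param genomes named list of [genome()] objects, or a data.frame/list of
#'   file paths with fields genome_id, gff, fasta (or genbank).
#' @param ortholog_table data.frame (group_id, genome_id, gene_id) or TSV
#'   path.
#' @param tfs list of factor definitions: each a list with `name`,
#'   `training_groups` (ortholog group ids with known sites), and optional
#'   `palindromic` flag (NA = auto-detect from the derived consensus).
#' @param out_dir output directory for stage files.
#' @param config a [scan_config()].
#' @param min_identity,min_window conserved-window calling parameters.
#' @param strict regulon assembly counts strong hits only.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes, ortholog_table, tfs, out_dir,
                            config = scan_config(), min_identity = 0.9,
                            min_window = 10, strict = FALSE, seed = 1L) {
  if (is.character(ortholog_table)) {
    if (!file.exists(ortholog_table))
      stop("validation error: ortholog table not found: ", ortholog_table)
    ortholog_table <- read_ortholog_table(ortholog_table)
  }
  if (!all(vapply(genomes, inherits, TRUE, "genome"))) {
    loaded <- lapply(genomes, function(entry) {
      entry <- as.list(entry)
      if (!is.null(entry$genbank)) {
        if (!file.exists(entry$genbank))
          stop("validation error: missing genome file: ", entry$genbank)
        read_genbank(entry$genbank)
      } else {
        if (!file.exists(entry$gff) || !file.exists(entry$fasta))
          stop("validation error: missing genome file(s) for entry")
        if (is.null(entry$genome_id)) read_genome_gff(entry$gff, entry$fasta)
        else read_genome_gff(entry$gff, entry$fasta,
                             genome_id = entry$genome_id)
      }
    })
    names(loaded) <- vapply(loaded, `[[`, character(1), "genome_id")
    genomes <- loaded
  }
  for (tf in tfs) {
    stopifnot(!is.null(tf$name), !is.null(tf$training_groups))
    missing <- setdiff(tf$training_groups, ortholog_table$group_id)
    if (length(missing) > 0)
      stop("validation error: unknown training group(s) for ", tf$name, ": ",
           paste(missing, collapse = ", "))
  }
  structure(list(genomes = genomes, ortholog_table = ortholog_table,
                 tfs = tfs, out_dir = out_dir, config = config,
                 min_identity = min_identity, min_window = min_window,
                 strict = strict, seed = as.integer(seed)),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full regulon-reconstruction pipeline
#'
#' Executes, per factor: phylogenetic footprinting of the training groups'
#' upstream regions, PWM construction from the harvested conserved windows
#' (palindrome-symmetrized when the consensus is self-complementary),
#' threshold calibration across all genomes, genome-wide scanning, weak-site
#' rescue, operon inference and persistence, regulon assembly and divergon
#' detection, plus motif-geometry reports. Stage outputs are written as TSV
#' (and MEME/FASTA where appropriate) under `out_dir`, every calibrated
#' threshold, per-genome hit fraction and rescued site (with its admitting
#' clause) is appended to `log.txt`, and `manifest.yaml` records inputs,
#' configuration, versions and a checksum of every declared output.
#'
#' @param pc a [pipeline_config()].
#' @return list with per-factor results (motif, calibration, hits, rescued,
#'   regulon, geometry), shared operons/divergons, and the manifest path.
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(pc$out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(pc$out_dir, name)
    df2 <- df
    for (cl in names(df2)) if (is.list(df2[[cl]]))
      df2[[cl]] <- vapply(df2[[cl]], function(x)
        paste(unlist(x), collapse = ","), character(1))
    utils::write.table(df2, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  genomes <- pc$genomes
  ortho <- pc$ortholog_table
  cfg <- pc$config
  say("pipeline start: %d genomes, %d ortholog groups, %d factor(s)",
      length(genomes), length(unique(ortho$group_id)), length(pc$tfs))
  bg <- genome_background(genomes)

  ## shared stages: operons and persistence
  operons_by_genome <- lapply(genomes, infer_operons, config = cfg)
  op_tab <- do.call(rbind, operons_by_genome)
  emit(op_tab, "operons.tsv")
  persistence <- check_operon_persistence(operons_by_genome, ortho,
                                          cfg$min_genomes)
  emit(persistence, "operon_persistence.tsv")

  results <- list()
  for (tf in pc$tfs) {
    say("[%s] footprinting %d training group(s)", tf$name,
        length(tf$training_groups))
    alignments <- list()
    windows <- list()
    for (grp in tf$training_groups) {
      rows <- ortho[ortho$group_id == grp, , drop = FALSE]
      regions <- lapply(seq_len(nrow(rows)), function(i)
        extract_upstream(genomes[[rows$genome_id[i]]], rows$gene_id[i], cfg))
      names(regions) <- rows$genome_id
      aln <- align_regions(regions, group_id = grp)
      alignments[[grp]] <- aln
      afa <- file.path(pc$out_dir,
                       sprintf("footprint_%s_%s.afa", tf$name, grp))
      write_alignment_fasta(aln, afa)
      outputs <- c(outputs, afa)
      win <- conserved_windows(aln, pc$min_identity, pc$min_window)
      if (nrow(win) > 0) windows[[grp]] <- win
    }
    windows <- do.call(rbind, windows)
    if (is.null(windows) || nrow(windows) == 0)
      stop("stage footprint [", tf$name, "]: no conserved windows found")
    emit(windows[, setdiff(names(windows), "row_offsets")],
         sprintf("footprint_windows_%s.tsv", tf$name))
    sites <- sites_from_windows(windows, alignments, tf_name = tf$name)
    say("[%s] %d training sites of width %d harvested", tf$name,
        length(sites$sites), nchar(sites$sites[1]))
    motif <- build_pwm(sites, background = bg)
    # re-register the harvested seeds on a common frame, then symmetrize
    training_regions <- unlist(lapply(tf$training_groups, function(grp) {
      rows <- ortho[ortho$group_id == grp, , drop = FALSE]
      lapply(seq_len(nrow(rows)), function(i)
        extract_upstream(genomes[[rows$genome_id[i]]], rows$gene_id[i], cfg))
    }), recursive = FALSE)
    motif <- refine_pwm(motif, training_regions)
    pal_flag <- tf$palindromic %||% NA
    if (is.na(pal_flag))
      pal_flag <- identical(revcomp(motif$consensus), motif$consensus)
    motif$palindromic <- isTRUE(pal_flag)
    if (motif$palindromic) motif <- symmetrize(motif)
    say("[%s] consensus %s%s", tf$name, motif$consensus,
        if (motif$palindromic) " (palindromic, symmetrized)" else "")
    write_meme(motif, file.path(pc$out_dir, sprintf("motif_%s.meme", tf$name)))
    write_pwm_tsv(motif, file.path(pc$out_dir,
                                   sprintf("motif_%s.tsv", tf$name)))
    outputs <- c(outputs,
                 file.path(pc$out_dir, sprintf("motif_%s.meme", tf$name)),
                 file.path(pc$out_dir, sprintf("motif_%s.tsv", tf$name)))

    training_genes <- split(
      ortho$gene_id[ortho$group_id %in% tf$training_groups],
      ortho$genome_id[ortho$group_id %in% tf$training_groups])
    cal <- calibrate_threshold(motif, genomes, training_genes, cfg)
    say("[%s] threshold %.4f (training coverage %.2f)", tf$name,
        cal$threshold, cal$training_coverage)
    for (i in seq_len(nrow(cal$per_genome)))
      say("[%s] genome %s: hit fraction %.4f (min admissible %.4f)",
          tf$name, cal$per_genome$genome_id[i],
          cal$per_genome$hit_fraction[i], cal$per_genome$min_admissible[i])
    emit(cal$per_genome, sprintf("calibration_%s.tsv", tf$name))

    hits <- scan_hits(motif, genomes, cal, cfg)
    rescued <- rescue_weak_sites(hits, ortho, cal, cfg)
    for (i in seq_len(nrow(rescued)))
      say("[%s] rescued weak site: genome %s gene %s position %d score %.3f (clause %s)",
          tf$name, rescued$genome_id[i], rescued$gene_id[i],
          rescued$position[i], rescued$score[i], rescued$rescue_clause[i])
    fh <- final_hits(hits, rescued)
    emit(fh, sprintf("hits_%s.tsv", tf$name))
    for (gn in genomes) {
      bed <- file.path(pc$out_dir,
                       sprintf("hits_%s_%s.bed", tf$name, gn$genome_id))
      write_hits_bed(fh, gn, motif$length, bed)
      outputs <- c(outputs, bed)
    }

    reg <- assemble_regulon(tf$name, fh, ortho, operons_by_genome, cfg,
                            strict = pc$strict)
    say("[%s] regulon: %d core group(s), %d singleton candidate(s)",
        tf$name, nrow(reg$core), nrow(reg$singletons))
    emit(reg$core, sprintf("regulon_core_%s.tsv", tf$name))
    emit(reg$members, sprintf("regulon_members_%s.tsv", tf$name))
    emit(reg$singletons, sprintf("regulon_singletons_%s.tsv", tf$name))

    divergons <- do.call(rbind, lapply(genomes, function(gn) {
      d <- detect_divergons(gn, fh, cfg, site_width = motif$length)
      if (nrow(d) > 0) d$genome_id <- gn$genome_id
      d
    }))
    emit(divergons[, setdiff(names(divergons), "shared_hits")],
         sprintf("divergons_%s.tsv", tf$name))

    pal <- check_palindrome(motif$consensus)
    geometry <- data.frame(tf_name = tf$name, consensus = motif$consensus,
                           is_palindrome = pal$is_palindrome,
                           length = pal$length, parity = pal$parity,
                           stringsAsFactors = FALSE)
    emit(geometry, sprintf("geometry_consensus_%s.tsv", tf$name))
    # helical phasing of genes carrying several sites
    strongh <- fh[fh$category == "strong", , drop = FALSE]
    phas <- list()
    for (key in unique(paste(strongh$genome_id, strongh$gene_id))) {
      sub <- strongh[paste(strongh$genome_id, strongh$gene_id) == key, ]
      centers <- sort(sub$position + motif$length / 2)
      if (length(centers) < 2) next
      ph <- site_phasing(centers, cfg$bp_per_turn)
      phas[[key]] <- data.frame(genome_id = sub$genome_id[1],
                                gene_id = sub$gene_id[1],
                                distances = paste(ph$distances, collapse = ","),
                                turns = paste(ph$turns, collapse = ","),
                                stringsAsFactors = FALSE)
    }
    phas <- if (length(phas) > 0) do.call(rbind, phas) else
      data.frame(genome_id = character(0), gene_id = character(0),
                 distances = character(0), turns = character(0))
    emit(phas, sprintf("geometry_phasing_%s.tsv", tf$name))

    results[[tf$name]] <- list(motif = motif, calibration = cal, hits = fh,
                               rescued = rescued, regulon = reg,
                               divergons = divergons,
                               geometry = list(palindrome = pal,
                                               phasing = phas))
  }
  say("pipeline done: %d stage output file(s) + log", length(outputs))
  writeLines(log_lines, log_path)
  outputs <- c(outputs, log_path)
  manifest <- list(
    package = "regulonscan",
    version = as.character(utils::packageVersion("regulonscan")),
    seed = pc$seed,
    genomes = vapply(genomes, `[[`, character(1), "genome_id"),
    n_ortholog_groups = length(unique(ortho$group_id)),
    factors = vapply(pc$tfs, `[[`, character(1), "name"),
    config = unclass(cfg),
    min_identity = pc$min_identity, min_window = pc$min_window,
    strict = pc$strict,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(pc$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  list(results = results, operons = operons_by_genome,
       persistence = persistence, manifest = manifest_path,
       log = log_path)
}
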
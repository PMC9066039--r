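# Self-consistent synthetic study generator with known ground truth.
#
# Emulates a 3-individual x 5-stage mammary-gland RNA-seq design: assembled
# transcript models (known "=" plus novel "u"/"i" with single-violation
# decoys), transcript sequences, coding-potential scores, NB counts with
# planted stage effects, FPKM consistent with the counts, planted correlated
# cis pairs, planted co-expression blocks, and a GWAS SNP table with an
# effect-enriched feature set.

#' Simulation configuration
#'
#' Defaults describe the emulated study: 15 samples (3 individuals x 5
#' stages -14/-10/-6/-2/+1 days around parturition), NB counts with common
#' dispersion, planted differential lncRNAs with a log2 fold change of 2 at
#' stages -2 and +1, cis pairs correlated at rho = 0.9 within 100 kb, and a
#' SNP universe in which an enriched subset carries effects with 5x the
#' background variance.
#'
#' @param seed integer RNG seed (mandatory for determinism).
#' @param n_transcripts total transcript models.
#' @param frac_known,frac_novel_u,frac_novel_i class-code proportions
#'   (must sum to 1).
#' @param frac_decoy fraction of novel transcripts that violate exactly one
#'   discovery filter each (types cycled).
#' @param n_de_lnc planted differentially expressed lncRNAs.
#' @param de_log2fc planted log2 fold change at stages -2 and +1.
#' @param nb_dispersion common NB dispersion (Var = mu + phi mu^2).
#' @param base_log_mean log of the typical per-sample count of a feature.
#' @param base_log_sd between-feature spread of log mean counts.
#' @param indiv_effect_sd SD of log-scale individual effects.
#' @param n_cis_pairs planted lncRNA-mRNA cis pairs.
#' @param cis_rho latent log-expression correlation of a planted pair.
#' @param cis_latent_sd SD of the shared latent log-expression profile.
#' @param n_module_blocks,module_block_size planted co-expression blocks
#'   (each block = `module_block_size` features sharing a latent
#'   stage-tracking profile).
#' @param module_amplitude log-scale amplitude of the block stage profiles.
#' @param n_snps,n_enriched_snps SNP universe size and the number of SNPs
#'   placed inside the enriched feature set.
#' @param beta_sd_background,beta_sd_enriched SDs of the marker-effect
#'   distributions (trait units).
#' @param n_genotyped genotyped animals behind each SNP's genotype counts.
#' @param genome `data.frame` with `chrom` and `length`.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_transcripts = 600L,
                              frac_known = 0.5,
                              frac_novel_u = 0.3,
                              frac_novel_i = 0.2,
                              frac_decoy = 0.15,
                              n_de_lnc = 40L,
                              de_log2fc = 2,
                              nb_dispersion = 0.1,
                              base_log_mean = log(100),
                              base_log_sd = 0.7,
                              indiv_effect_sd = 0.1,
                              n_cis_pairs = 20L,
                              cis_rho = 0.9,
                              cis_latent_sd = 1,
                              n_module_blocks = 3L,
                              module_block_size = 20L,
                              module_amplitude = 1.5,
                              n_snps = 5000L,
                              n_enriched_snps = 100L,
                              beta_sd_background = 0.1,
                              beta_sd_enriched = 0.1 * sqrt(5),
                              n_genotyped = 985L,
                              genome = data.frame(
                                chrom = c("chr1", "chr2", "chr3"),
                                length = c(6e7, 5e7, 4e7))) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              frac_known = frac_known, frac_novel_u = frac_novel_u,
              frac_novel_i = frac_novel_i, frac_decoy = frac_decoy,
              n_de_lnc = as.integer(n_de_lnc), de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion, base_log_mean = base_log_mean,
              base_log_sd = base_log_sd, indiv_effect_sd = indiv_effect_sd,
              n_cis_pairs = as.integer(n_cis_pairs), cis_rho = cis_rho,
              cis_latent_sd = cis_latent_sd,
              n_module_blocks = as.integer(n_module_blocks),
              module_block_size = as.integer(module_block_size),
              module_amplitude = module_amplitude,
              n_snps = as.integer(n_snps),
              n_enriched_snps = as.integer(n_enriched_snps),
              beta_sd_background = beta_sd_background,
              beta_sd_enriched = beta_sd_enriched,
              n_genotyped = as.integer(n_genotyped), genome = genome)
  fr <- cfg$frac_known + cfg$frac_novel_u + cfg$frac_novel_i
  if (abs(fr - 1) > 1e-8) stopf("class proportions must sum to 1 (got %.4f)", fr)
  if (cfg$n_enriched_snps > cfg$n_snps) {
    stopf("n_enriched_snps exceeds n_snps")
  }
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (abs(cfg$cis_rho) > 1) stopf("cis_rho must be in [-1, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random sequence guaranteed to have max ORF < max_orf: rejection sampling
# with a deterministic fallback that deletes every ATG.
seq_without_long_orf <- function(len, max_orf = 360L, tries = 25L) {
  for (i in seq_len(tries)) {
    s <- random_seq(len)
    if (find_max_orf(s) < max_orf) return(s)
  }
  gsub("ATG", "ATT", random_seq(len), fixed = TRUE)
}

# Random sequence carrying one ORF of orf_len nt (multiple of 3, >= 9).
seq_with_long_orf <- function(len, orf_len = 399L) {
  stopifnot(len >= orf_len)
  ncod <- orf_len / 3L - 2L
  body <- replicate(ncod, {
    repeat {
      cod <- random_seq(3L)
      if (!(cod %in% c(ORF_STOPS, "ATG"))) return(cod)
    }
  })
  orf <- paste0("ATG", paste(body, collapse = ""), "TAA")
  pre_len <- (len - orf_len) %/% 2L
  pre_len <- pre_len - (pre_len %% 3L)  # keep the ORF in frame 1 of the insert
  pre <- if (pre_len > 0) gsub("ATG", "ATT", random_seq(pre_len), fixed = TRUE) else ""
  post_len <- len - orf_len - nchar(pre)
  post <- if (post_len > 0) random_seq(post_len) else ""
  paste0(pre, orf, post)
}

DECOY_TYPES <- c("support", "class_code", "length", "exon_count",
                 "expression", "orf", "coding_potential")

# Exon layout for one transcript. Returns data.frame(start, end) relative to
# a genomic start position.
make_exons <- function(gstart, n_exons, exon_lens, intron_lens) {
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- gstart
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + (if (i < n_exons) intron_lens[i] else 0L) + 1L
  }
  data.frame(start = starts, end = ends)
}

#' Simulate a complete synthetic study
#'
#' Writes GTF + FASTA + coding-score TSV + counts/FPKM/design TSVs (15
#' samples) + SNP TSV into `dir` and returns the ground truth. Output is
#' byte-identical for identical configurations (the seed lives in the
#' config). FPKM is derived from the simulated counts as
#' `count / (len_kb * total/1e6)` so the two layers are consistent.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return A list with `paths` (named file paths), `truth` (planted ground
#'   truth) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = tempfile("sim")) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_transcripts
  n_known <- round(n * config$frac_known)
  n_u <- round(n * config$frac_novel_u)
  n_i <- n - n_known - n_u
  n_novel <- n_u + n_i
  n_decoy <- round(n_novel * config$frac_decoy)
  n_clean <- n_novel - n_decoy
  if (n_clean < config$n_cis_pairs + config$n_de_lnc +
      3L * config$n_module_blocks) {
    stopf("infeasible config: %d clean novel transcripts < %d planted (cis + DE + module)",
          n_clean, config$n_cis_pairs + config$n_de_lnc +
            3L * config$n_module_blocks)
  }
  if (n_known < config$n_cis_pairs + config$n_module_blocks *
      (config$module_block_size - 3L)) {
    stopf("infeasible config: not enough known genes for cis pairs and module blocks")
  }
  if (config$n_enriched_snps > 0 && config$n_de_lnc == 0) {
    stopf("infeasible config: enriched SNPs require planted DE lncRNAs")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  local_seed(config$seed, {
    ## ---- transcript models -------------------------------------------------
    known_ids <- sprintf("KNOWN.%04d", seq_len(n_known))
    novel_ids <- sprintf("TU.%04d", seq_len(n_novel))
    ids <- c(known_ids, novel_ids)
    cc <- c(rep("=", n_known), rep("u", n_u), rep("i", n_i))
    # shuffle novel class codes so u/i are not blockwise
    cc[(n_known + 1):n] <- sample(cc[(n_known + 1):n])

    decoy_idx <- if (n_decoy > 0) n_known + sample.int(n_novel, n_decoy) else integer(0)
    decoy_type <- stats::setNames(rep(NA_character_, n), ids)
    if (n_decoy > 0) {
      decoy_type[decoy_idx] <- rep_len(DECOY_TYPES, n_decoy)
    }
    clean_novel <- setdiff((n_known + 1):n, decoy_idx)

    occ <- pmin(15L, 1L + stats::rpois(n, 4))
    occ[occ < 2L] <- 2L
    asm <- sample(1:2, n, replace = TRUE)
    sup_dec <- which(decoy_type == "support")
    occ[sup_dec] <- 1L; asm[sup_dec] <- 1L
    cc[which(decoy_type == "class_code")] <- "j"

    n_ex <- sample(2:5, n, replace = TRUE)
    n_ex[which(decoy_type == "exon_count")] <- 1L
    n_ex[which(decoy_type == "length")] <- 2L  # 2 exons of 60-90 nt < 200 nt
    exon_lens <- lapply(seq_len(n), function(f) {
      if (!is.na(decoy_type[f]) && decoy_type[f] == "length") {
        # total < 200 nt but still >= 2 exons
        sample(60:90, n_ex[f], replace = TRUE)
      } else if (!is.na(decoy_type[f]) && decoy_type[f] == "orf") {
        lens <- sample(300:800, n_ex[f], replace = TRUE)
        lens[1] <- max(lens[1], 450L)  # room for the planted ORF
        lens
      } else if (n_ex[f] == 1L) {
        sample(600:1500, 1L)
      } else {
        sample(150:800, n_ex[f], replace = TRUE)
      }
    })

    genome <- config$genome
    chrom_of <- sample(genome$chrom, n, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    span_max <- vapply(exon_lens, sum, 0L) + 5000L * (n_ex - 1L)
    gstart <- vapply(seq_len(n), function(f) {
      L <- genome$length[genome$chrom == chrom_of[f]]
      as.integer(floor(stats::runif(1, 1, L - span_max[f] - 2e5)))
    }, 0L)

    ## planted feature assignment (disjoint sets of clean novel lncRNAs)
    pool <- sample(clean_novel)
    cis_lnc <- pool[seq_len(config$n_cis_pairs)]
    pool <- setdiff(pool, cis_lnc)
    de_lnc <- pool[seq_len(config$n_de_lnc)]
    pool <- setdiff(pool, de_lnc)
    block_lnc <- lapply(seq_len(config$n_module_blocks), function(b) {
      out <- pool[seq_len(3L)]
      pool <<- setdiff(pool, out)
      out
    })
    gene_pool <- sample(seq_len(n_known))
    cis_gene <- gene_pool[seq_len(config$n_cis_pairs)]
    gene_pool <- setdiff(gene_pool, cis_gene)
    block_gene <- lapply(seq_len(config$n_module_blocks), function(b) {
      out <- gene_pool[seq_len(config$module_block_size - 3L)]
      gene_pool <<- setdiff(gene_pool, out)
      out
    })

    # relocate each cis gene within 100 kb of its lncRNA
    for (k in seq_len(config$n_cis_pairs)) {
      lf <- cis_lnc[k]; gf <- cis_gene[k]
      chrom_of[gf] <- chrom_of[lf]
      gap <- sample(1000:50000, 1L)
      gstart[gf] <- gstart[lf] + span_max[lf] + gap
    }

    exons <- lapply(seq_len(n), function(f) {
      introns <- if (n_ex[f] > 1L) sample(100:5000, n_ex[f] - 1L,
                                          replace = TRUE) else integer(0)
      make_exons(gstart[f], n_ex[f], exon_lens[[f]], introns)
    })
    tlen <- vapply(exons, function(e) sum(e$end - e$start + 1L), 0L)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    ## sequences: novel transcripts get no long ORF except the orf decoys
    seqs <- vapply(seq_len(n), function(f) {
      if (f <= n_known) {
        random_seq(tlen[f])
      } else if (!is.na(decoy_type[f]) && decoy_type[f] == "orf") {
        seq_with_long_orf(tlen[f], orf_len = 399L)
      } else {
        seq_without_long_orf(tlen[f])
      }
    }, "")
    names(seqs) <- ids

    transcripts <- lapply(seq_len(n), function(f) {
      transcript_model(ids[f],
                       gene_id = if (f <= n_known)
                         sprintf("GENE.%04d", f) else
                           sprintf("XLOC_%06d", f - n_known),
                       chrom = chrom_of[f], strand = strand[f],
                       exons = exons[[f]], class_code = cc[f],
                       assembler_support = asm[f], sample_occurrence = occ[f])
    })
    names(transcripts) <- ids

    ## coding-potential scores
    scores <- data.frame(transcript_id = ids,
                         cpc_score = stats::runif(n, -3, -0.2),
                         plek_score = stats::runif(n, -3, -0.2),
                         cnci_score = stats::runif(n, -3, -0.2),
                         stringsAsFactors = FALSE)
    kn <- seq_len(n_known)
    scores$cpc_score[kn] <- stats::runif(n_known, 0.5, 5)
    scores$plek_score[kn] <- stats::runif(n_known, 0.5, 5)
    scores$cnci_score[kn] <- stats::runif(n_known, 0.5, 5)
    cod_dec <- which(decoy_type == "coding_potential")
    if (length(cod_dec) > 0) {
      col <- sample(c("cpc_score", "plek_score", "cnci_score"),
                    length(cod_dec), replace = TRUE)
      for (k in seq_along(cod_dec)) {
        scores[[col[k]]][cod_dec[k]] <- stats::runif(1, 0.5, 3)
      }
    }

    ## ---- expression --------------------------------------------------------
    individuals <- paste0("I", 1:3)
    design <- expand.grid(stage = STAGE_LEVELS, individual = individuals,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design <- design[order(design$individual,
                           match(design$stage, STAGE_LEVELS)), ]
    design <- data.frame(sample_id = paste0(design$individual, "_",
                                            design$stage),
                         individual = design$individual, stage = design$stage,
                         stringsAsFactors = FALSE)
    ns <- nrow(design)
    stage_idx <- match(design$stage, STAGE_LEVELS)

    log_mu <- stats::rnorm(n, config$base_log_mean, config$base_log_sd)
    ind_eff <- stats::setNames(stats::rnorm(3, 0, config$indiv_effect_sd),
                               individuals)

    stage_eff <- matrix(0, n, 5)
    stage_eff[de_lnc, 4:5] <- config$de_log2fc * log(2)
    block_members <- list()
    for (b in seq_len(config$n_module_blocks)) {
      members <- c(block_lnc[[b]], block_gene[[b]])
      block_members[[b]] <- ids[members]
      prof <- switch(((b - 1L) %% 3L) + 1L,
                     c(0, 0, 0, 0, 1),    # tracks day +1
                     c(1, 0, 0, 0, 0),    # tracks day -14
                     c(1, 0.5, 0, -0.5, -1))  # monotone decline
      stage_eff[members, ] <- stage_eff[members, , drop = FALSE] +
        matrix(rep(prof * config$module_amplitude, each = length(members)),
               nrow = length(members)) +
        stats::rnorm(length(members) * 5, 0, 0.1)
    }
    names(block_members) <- paste0("block", seq_len(config$n_module_blocks))

    latent <- matrix(0, n, ns)
    for (k in seq_len(config$n_cis_pairs)) {
      z <- stats::rnorm(ns)
      rho <- config$cis_rho
      latent[cis_lnc[k], ] <- config$cis_latent_sd *
        (sqrt(abs(rho)) * z + sqrt(1 - abs(rho)) * stats::rnorm(ns))
      # the gene shares the latent profile; its sign carries sign(rho)
      latent[cis_gene[k], ] <- config$cis_latent_sd *
        (sign(rho) * sqrt(abs(rho)) * z +
           sqrt(1 - abs(rho)) * stats::rnorm(ns))
    }

    mu_mat <- exp(matrix(log_mu, n, ns) +
                    matrix(ind_eff[design$individual], n, ns, byrow = TRUE) +
                    stage_eff[, stage_idx] + latent)
    mu_mat[which(decoy_type == "expression"), ] <- 0
    counts <- matrix(stats::rnbinom(n * ns, mu = mu_mat,
                                    size = 1 / max(config$nb_dispersion, 1e-8)),
                     n, ns, dimnames = list(ids, design$sample_id))
    totals <- colSums(counts)
    fpkm <- counts / outer(tlen / 1000, totals / 1e6)
    expr <- expression_matrix(counts, fpkm, design)

    ## ---- SNPs --------------------------------------------------------------
    de_loci <- transcript_loci(transcripts[de_lnc])
    n_bg <- config$n_snps - config$n_enriched_snps
    bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    bg_pos <- vapply(bg_chrom, function(ch) {
      as.integer(floor(stats::runif(1, 1,
                                    genome$length[genome$chrom == ch] + 1)))
    }, 0L)
    if (config$n_enriched_snps > 0) {
      pick <- sample.int(nrow(de_loci), config$n_enriched_snps, replace = TRUE)
      en_chrom <- de_loci$chrom[pick]
      en_pos <- vapply(seq_along(pick), function(k) {
        as.integer(floor(stats::runif(1, de_loci$start[pick[k]],
                                      de_loci$end[pick[k]] + 1)))
      }, 0L)
    } else {
      en_chrom <- character(0); en_pos <- integer(0)
    }
    beta <- c(stats::rnorm(n_bg, 0, config$beta_sd_background),
              stats::rnorm(config$n_enriched_snps, 0,
                           config$beta_sd_enriched))
    pfreq <- stats::runif(config$n_snps, 0.05, 0.45)
    geno <- vapply(pfreq, function(p) {
      drop(stats::rmultinom(1, config$n_genotyped,
                            c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    }, numeric(3))
    snps <- data.frame(id = sprintf("SNP%06d", seq_len(config$n_snps)),
                       chrom = c(bg_chrom, en_chrom),
                       pos = c(bg_pos, en_pos), beta = beta,
                       n_AA = geno[1, ], n_Aa = geno[2, ], n_aa = geno[3, ],
                       stringsAsFactors = FALSE)
    enriched_snp_ids <- snps$id[seq.int(n_bg + 1, length.out =
                                          config$n_enriched_snps)]
    snps <- snps[order(snps$chrom, snps$pos), ]
    rownames(snps) <- NULL

    ## ---- write files -------------------------------------------------------
    paths <- list(gtf = file.path(dir, "transcripts.gtf"),
                  fasta = file.path(dir, "transcripts.fa"),
                  scores = file.path(dir, "coding_scores.tsv"),
                  counts = file.path(dir, "counts.tsv"),
                  fpkm = file.path(dir, "fpkm.tsv"),
                  design = file.path(dir, "design.tsv"),
                  snps = file.path(dir, "snps.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_gtf(transcripts, paths$gtf)
    write_fasta(seqs, paths$fasta)
    write_tsv(scores, paths$scores)
    write_expression_matrix(expr, paths$counts, paths$fpkm, paths$design)
    write_snp_effects(snps, paths$snps)

    truth <- list(
      lncrna_ids = ids[clean_novel],
      known_ids = known_ids,
      decoys = data.frame(transcript_id = ids[decoy_idx],
                          type = unname(decoy_type[decoy_idx]),
                          stringsAsFactors = FALSE),
      de_ids = ids[de_lnc],
      de_contrasts = c("-2vs-14", "+1vs-14"),
      cis_pairs = data.frame(lncrna_id = ids[cis_lnc],
                             gene_id = ids[cis_gene],
                             stringsAsFactors = FALSE),
      enriched_set = "de_lncrna",
      enriched_snp_ids = enriched_snp_ids,
      module_blocks = block_members,
      exchangeable = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    list(paths = paths, truth = truth, config = config)
  })
}

#' Simulate a SNP table under the exchangeable null
#'
#' Same placement scheme as [simulate_dataset()] (a share of SNPs inside the
#' given feature set, the rest uniform on the genome) but every marker effect
#' is drawn from the background distribution, so in-set and background SNPs
#' are exchangeable and the enrichment p-value is uniform by construction.
#'
#' @param config a [simulation_config()]; `n_enriched_snps` controls how many
#'   SNPs land inside the set (their effects are background-distributed).
#' @param fs a [feature_set()] to place SNPs into.
#' @param path optional TSV output path.
#' @return A list with `snps` (`data.frame`) and `truth`
#'   (`exchangeable = TRUE`, `in_set_ids`).
#' @export
simulate_null_gwas <- function(config, fs, path = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(fs, "feature_set"))
  genome <- config$genome
  local_seed(config$seed, {
    n_in <- config$n_enriched_snps
    n_bg <- config$n_snps - n_in
    bg_chrom <- sample(genome$chrom, n_bg, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    bg_pos <- vapply(bg_chrom, function(ch) {
      as.integer(floor(stats::runif(1, 1,
                                    genome$length[genome$chrom == ch] + 1)))
    }, 0L)
    iv <- fs$intervals
    pick <- sample.int(nrow(iv), n_in, replace = TRUE)
    in_chrom <- iv$chrom[pick]
    in_pos <- vapply(seq_along(pick), function(k) {
      as.integer(floor(stats::runif(1, iv$start[pick[k]],
                                    iv$end[pick[k]] + 1)))
    }, 0L)
    beta <- stats::rnorm(config$n_snps, 0, config$beta_sd_background)
    pfreq <- stats::runif(config$n_snps, 0.05, 0.45)
    geno <- vapply(pfreq, function(p) {
      drop(stats::rmultinom(1, config$n_genotyped,
                            c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    }, numeric(3))
    snps <- data.frame(id = sprintf("SNP%06d", seq_len(config$n_snps)),
                       chrom = c(bg_chrom, in_chrom),
                       pos = c(bg_pos, in_pos), beta = beta,
                       n_AA = geno[1, ], n_Aa = geno[2, ], n_aa = geno[3, ],
                       stringsAsFactors = FALSE)
    in_set_ids <- snps$id[seq.int(n_bg + 1, length.out = n_in)]
    snps <- snps[order(snps$chrom, snps$pos), ]
    rownames(snps) <- NULL
    if (!is.null(path)) write_snp_effects(snps, path)
    list(snps = snps, truth = list(exchangeable = TRUE,
                                   in_set_ids = in_set_ids))
  })
}
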
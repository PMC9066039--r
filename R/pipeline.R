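# Pipeline orchestration: simulate -> discover -> de -> cluster -> enrich ->
# targets -> modules, with one config, seeded determinism and per-stage
# manifests.

PIPELINE_STAGES <- c("simulate", "discover", "de", "cluster", "enrich",
                     "targets", "modules")

#' Default pipeline configuration
#'
#' A flat named list: stage toggles (`run_<stage>`), per-stage parameters and
#' the global seed, which is split deterministically into per-stage seeds so
#' toggling one stage never perturbs another's randomness.
#'
#' @param seed global seed.
#' @param ... overrides of any default entry.
#' @return Named list.
#' @export
default_pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(seed = as.integer(seed),
              run_simulate = TRUE, run_discover = TRUE, run_de = TRUE,
              run_cluster = TRUE, run_enrich = TRUE, run_targets = TRUE,
              run_modules = TRUE,
              sim_n_transcripts = 400L, sim_n_snps = 2000L,
              sim_n_enriched_snps = 60L, sim_n_de_lnc = 30L,
              min_fpkm = 0.3, min_len = 200L, min_exons = 2L,
              max_orf = 360L, min_support = 2L, coding_mode = "any",
              de_alpha = 0.05,
              gap_B = 20L, gap_k_max = 8L,
              enrich_flank = 10000L, enrich_n_perm = 2000L,
              target_window = 100000L, target_alpha = 0.05,
              module_min_size = 5L, module_max_features = 200L,
              lncrna_bed = NA_character_,
              input_dir = NA_character_)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a flat `key = value` pipeline config file
#'
#' Lines are `key = value`; `#` starts a comment. Values are coerced to
#' numeric or logical where possible.
#'
#' @param path config file path.
#' @return Named list merged over [default_pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (v %in% c("TRUE", "FALSE", "true", "false")) {
      return(toupper(v) == "TRUE")
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(if (num == round(num)) as.integer(num) else num)
    v
  })
  names(vals) <- vapply(kv, `[[`, "", 1)
  cfg <- default_pipeline_config()
  cfg[names(vals)] <- vals
  cfg
}

write_manifest <- function(stage_dir, stage, params, inputs, seed) {
  hashes <- if (length(inputs) > 0) {
    h <- tools::md5sum(unlist(inputs))
    # keyed by file name, not absolute path, so identical runs in different
    # directories produce byte-identical manifests
    stats::setNames(as.list(unname(h)), basename(names(h)))
  } else {
    list()
  }
  manifest <- list(stage = stage, seed = seed, params = params,
                   input_md5 = hashes)
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Runs the enabled stages in dependency order inside `out_dir`, each stage
#' writing its outputs plus a manifest (parameters, derived seed, md5 of its
#' inputs). A failed stage aborts downstream stages; earlier outputs are
#' retained. With `run_simulate = FALSE` the stage inputs are read from
#' `config$input_dir`; with `run_discover = FALSE` a precomputed lncRNA BED
#' (`config$lncrna_bed`) feeds the downstream stages.
#'
#' @param config named list, see [default_pipeline_config()].
#' @param out_dir run directory (created).
#' @return Invisibly, a list of per-stage results plus the summary (also
#'   written to `summary.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  summary <- list(seed = config$seed)
  seeds <- stats::setNames(lapply(seq_along(PIPELINE_STAGES), function(i)
    derive_seed(config$seed, i)), PIPELINE_STAGES)

  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }

  ## simulate ----------------------------------------------------------------
  if (isTRUE(config$run_simulate)) {
    d <- stage_dir("simulate")
    sim_cfg <- simulation_config(seed = seeds$simulate,
                                 n_transcripts = config$sim_n_transcripts,
                                 n_snps = config$sim_n_snps,
                                 n_enriched_snps = config$sim_n_enriched_snps,
                                 n_de_lnc = config$sim_n_de_lnc)
    res$simulate <- simulate_dataset(sim_cfg, d)
    input_dir <- d
    write_manifest(d, "simulate", sim_cfg[setdiff(names(sim_cfg), "genome")],
                   list(), seeds$simulate)
  } else {
    input_dir <- config$input_dir
    if (is.na(input_dir) || !dir.exists(input_dir)) {
      stopf("run_simulate is FALSE and input_dir does not exist")
    }
  }
  paths <- list(gtf = file.path(input_dir, "transcripts.gtf"),
                fasta = file.path(input_dir, "transcripts.fa"),
                scores = file.path(input_dir, "coding_scores.tsv"),
                counts = file.path(input_dir, "counts.tsv"),
                fpkm = file.path(input_dir, "fpkm.tsv"),
                design = file.path(input_dir, "design.tsv"),
                snps = file.path(input_dir, "snps.tsv"))
  missing <- unlist(paths)[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    stopf("missing pipeline input(s): %s", paste(missing, collapse = ", "))
  }

  transcripts <- read_gtf(paths$gtf)
  transcripts <- attach_sequences(transcripts, read_fasta(paths$fasta))
  expr <- read_expression_matrix(paths$counts, paths$fpkm, paths$design)
  scores <- read_tsv(paths$scores)
  loci <- transcript_loci(transcripts)

  ## discover ----------------------------------------------------------------
  if (isTRUE(config$run_discover)) {
    d <- stage_dir("discover")
    params <- discovery_params(min_len = config$min_len,
                               min_exons = config$min_exons,
                               min_fpkm = config$min_fpkm,
                               max_orf = config$max_orf,
                               min_support = config$min_support,
                               coding_mode = config$coding_mode)
    disc <- run_discovery_cascade(transcripts, expr, scores, params)
    res$discover <- disc
    lnc_bed <- loci[loci$feature_id %in% disc$lncrna_ids, ]
    write_bed(lnc_bed, file.path(d, "lncrna.bed"))
    write_tsv(disc$report, file.path(d, "discovery_report.tsv"))
    summary$n_lncrna <- length(disc$lncrna_ids)
    summary$n_known <- length(disc$known_ids)
    write_manifest(d, "discover", params,
                   paths[c("gtf", "fasta", "scores", "fpkm")], NA)
    lncrna_ids <- disc$lncrna_ids
  } else {
    if (is.na(config$lncrna_bed)) {
      stopf("run_discover is FALSE: provide config$lncrna_bed")
    }
    lncrna_ids <- read_bed(config$lncrna_bed)$feature_id
  }
  known_ids <- names(transcripts)[vapply(transcripts, `[[`, "",
                                         "class_code") == "="]

  ## de ----------------------------------------------------------------------
  de_feature_ids <- character(0)
  if (isTRUE(config$run_de)) {
    d <- stage_dir("de")
    de <- run_de_contrasts(expr, alpha = config$de_alpha)
    res$de <- de
    lnc_tab <- de$table[de$table$feature_id %in% lncrna_ids, ]
    for (ct in unique(lnc_tab$contrast)) {
      write_tsv(lnc_tab[lnc_tab$contrast == ct, ],
                file.path(d, paste0("de_", gsub("[^0-9A-Za-z]", "_", ct),
                                    ".tsv")))
    }
    de_feature_ids <- unique(lnc_tab$feature_id[lnc_tab$de])
    de_sum <- do.call(rbind, lapply(unique(lnc_tab$contrast), function(ct) {
      s <- lnc_tab[lnc_tab$contrast == ct & lnc_tab$de, ]
      data.frame(contrast = ct, n_de = nrow(s),
                 up = sum(s$direction == "up"),
                 down = sum(s$direction == "down"))
    }))
    write_tsv(de_sum, file.path(d, "de_summary.tsv"))
    summary$n_de_lncrna <- length(de_feature_ids)
    summary$dispersion <- de$dispersion
    write_manifest(d, "de", list(alpha = config$de_alpha),
                   paths[c("counts", "design")], NA)
  }

  ## cluster -----------------------------------------------------------------
  if (isTRUE(config$run_cluster) && length(de_feature_ids) >= 10) {
    d <- stage_dir("cluster")
    prof <- suppressWarnings(stage_profiles(expr, de_feature_ids))
    k_max <- min(config$gap_k_max, nrow(prof) - 1L)
    gap <- gap_statistic_select_k(prof, k_range = 1:k_max, B = config$gap_B,
                                  seed = seeds$cluster)
    cl <- cluster_patterns(prof, gap$k, seed = seeds$cluster)
    res$cluster <- list(gap = gap, clusters = cl)
    write_tsv(data.frame(feature_id = names(cl$labels),
                         cluster = cl$labels), file.path(d, "clusters.tsv"))
    write_tsv(gap$curve, file.path(d, "gap_curve.tsv"))
    summary$k_clusters <- gap$k
    write_manifest(d, "cluster", list(B = config$gap_B, k_max = k_max),
                   paths["fpkm"], seeds$cluster)
  }

  ## enrich ------------------------------------------------------------------
  if (isTRUE(config$run_enrich)) {
    d <- stage_dir("enrich")
    snps <- read_snp_effects(paths$snps)
    qc <- if (all(c("n_AA", "n_Aa", "n_aa") %in% names(snps))) {
      snp_qc(snps)
    } else {
      list(snps = snps, report = NULL)
    }
    sets <- list(lncrna = lncrna_ids)
    if (length(de_feature_ids) > 0) sets$de_lncrna <- de_feature_ids
    enr <- lapply(names(sets), function(nm) {
      fs <- feature_set(nm, loci[loci$feature_id %in% sets[[nm]], ],
                        flank = config$enrich_flank)
      permutation_enrichment(qc$snps, fs, n_perm = config$enrich_n_perm,
                             seed = seeds$enrich)
    })
    names(enr) <- names(sets)
    res$enrich <- enr
    etab <- do.call(rbind, lapply(enr, function(e) {
      data.frame(feature_set = e$feature_set, m_g = e$m_g, t_obs = e$t_obs,
                 fold = e$fold, p_emp = e$p_emp)
    }))
    write_tsv(etab, file.path(d, "enrichment.tsv"))
    for (nm in names(enr)) {
      write_tsv(data.frame(null_sum = enr[[nm]]$null_sums),
                file.path(d, paste0("null_", nm, ".tsv")))
    }
    summary$enrichment <- lapply(enr, function(e)
      list(m_g = e$m_g, fold = e$fold, p = e$p_emp))
    write_manifest(d, "enrich",
                   list(flank = config$enrich_flank,
                        n_perm = config$enrich_n_perm),
                   paths["snps"], seeds$enrich)
  }

  ## targets -----------------------------------------------------------------
  target_pairs <- NULL
  if (isTRUE(config$run_targets)) {
    d <- stage_dir("targets")
    lnc_loci <- loci[loci$feature_id %in% lncrna_ids, ]
    gene_loci <- loci[loci$feature_id %in% known_ids, ]
    cand <- cis_candidates(lnc_loci, gene_loci, window = config$target_window)
    target_pairs <- suppressWarnings(
      predict_targets(cand, expr, alpha = config$target_alpha))
    res$targets <- target_pairs
    write_tsv(target_pairs, file.path(d, "target_pairs.tsv"))
    summary$n_candidate_pairs <- nrow(cand)
    summary$n_significant_pairs <- sum(target_pairs$significant)
    write_manifest(d, "targets",
                   list(window = config$target_window,
                        alpha = config$target_alpha),
                   paths[c("gtf", "fpkm")], NA)
  }

  ## modules -----------------------------------------------------------------
  if (isTRUE(config$run_modules)) {
    d <- stage_dir("modules")
    feats <- unique(c(de_feature_ids,
                      if (!is.null(target_pairs))
                        target_pairs$gene_id[target_pairs$significant]))
    pool <- setdiff(c(lncrna_ids, known_ids), feats)
    if (length(feats) < config$module_max_features && length(pool) > 0) {
      vars <- apply(expr$fpkm[pool, , drop = FALSE], 1, stats::var)
      extra <- names(sort(vars, decreasing = TRUE))
      feats <- c(feats, utils::head(extra,
                                    config$module_max_features - length(feats)))
    }
    feats <- utils::head(feats, config$module_max_features)
    m <- log2(expr$fpkm[feats, , drop = FALSE] + 1)
    m <- m[apply(m, 1, stats::sd) > 0, , drop = FALSE]
    power <- suppressWarnings(pick_soft_power(m))
    tom <- tom_from_expression(m, power)
    labels <- detect_modules(tom, min_module_size = config$module_min_size)
    assoc <- module_trait_association(labels, m, expr$design)
    res$modules <- list(power = as.integer(power), labels = labels,
                        association = assoc)
    write_tsv(data.frame(feature_id = names(labels), module = labels),
              file.path(d, "module_labels.tsv"))
    write_tsv(data.frame(module = rownames(assoc$eigengenes),
                         assoc$eigengenes, check.names = FALSE),
              file.path(d, "eigengenes.tsv"))
    rp <- data.frame(module = rownames(assoc$r))
    for (s in colnames(assoc$r)) {
      rp[[paste0("r_", s)]] <- assoc$r[, s]
      rp[[paste0("p_", s)]] <- assoc$p[, s]
    }
    write_tsv(rp, file.path(d, "module_stage_association.tsv"))
    summary$n_modules <- length(unique(labels[labels > 0]))
    summary$soft_power <- as.integer(power)
    write_manifest(d, "modules",
                   list(min_module_size = config$module_min_size,
                        power = as.integer(power)),
                   paths["fpkm"], NA)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$summary <- summary
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches `lactnet <subcommand> [--config FILE] [--seed N] [--out DIR]`
#' where subcommand is one of `simulate`, `run-all`, or a single stage name
#' (`discover`, `de`, `cluster`, `enrich`, `targets`, `modules` — run with
#' the other stages toggled off against `--input-dir`).
#'
#' @param argv character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
lactnet_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    cat("usage: lactnet <simulate|run-all|discover|de|cluster|enrich|targets|modules>",
        "[--config FILE] [--seed N] [--out DIR] [--input-dir DIR]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  get_opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  cfg <- if (!is.null(get_opt("--config"))) {
    read_pipeline_config(get_opt("--config"))
  } else {
    default_pipeline_config()
  }
  seed <- get_opt("--seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- get_opt("--out", file.path(getwd(), "lactnet_run"))
  input_dir <- get_opt("--input-dir")
  if (!is.null(input_dir)) cfg$input_dir <- input_dir

  if (cmd == "simulate") {
    for (s in PIPELINE_STAGES[-1]) cfg[[paste0("run_", s)]] <- FALSE
  } else if (cmd %in% PIPELINE_STAGES[-1]) {
    for (s in PIPELINE_STAGES) cfg[[paste0("run_", s)]] <- s == cmd
    # single non-simulate stage: upstream products must be provided
    if (cmd != "discover") cfg$run_discover <- FALSE
    cfg$run_simulate <- FALSE
    if (cmd %in% c("cluster", "enrich", "modules")) cfg$run_de <- TRUE
    if (cmd == "modules") cfg$run_targets <- TRUE
  } else if (cmd != "run-all") {
    stopf("unknown subcommand: %s", cmd)
  }
  run_pipeline(cfg, out)
  message("lactnet: outputs written to ", out)
  invisible(0L)
}
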
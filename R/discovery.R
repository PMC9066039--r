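# lncRNA discovery filter cascade.
#
# Turns assembled transcript models into a candidate lncRNA set via the
# multi-step filter: assembly support, class code, length/exon count,
# expression, maximum ORF, coding potential.

ORF_STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of the sense-strand sequence for
#' ATG-initiated open reading frames terminated by the first in-frame stop
#' codon (TAA/TAG/TGA). The returned length is in nucleotides and includes
#' the stop codon, so the conventional "< 120 amino acids" lncRNA criterion
#' corresponds to a maximum ORF < 360 nt. Codons containing `N` never match a
#' start or stop. An ATG with no downstream in-frame stop does not form an
#' ORF.
#'
#' @param sequence a single string over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return Integer ORF length in nt (0 if no ORF).
#' @export
find_max_orf <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stopf("sequence must be a single string")
  }
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) {
    stopf("sequence contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(s)
  best <- 0L
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 2L) next
    pos <- seq.int(f + 1L, by = 3L, length.out = ncod)
    codons <- substring(s, pos, pos + 2L)
    start_idx <- which(codons == "ATG")
    stop_idx <- which(codons %in% ORF_STOPS)
    if (length(start_idx) == 0L || length(stop_idx) == 0L) next
    # first in-frame stop strictly after each start (a start is never a stop)
    k <- findInterval(start_idx, stop_idx) + 1L
    has_stop <- k <= length(stop_idx)
    if (!any(has_stop)) next
    len <- (stop_idx[k[has_stop]] - start_idx[has_stop] + 1L) * 3L
    best <- max(best, len)
  }
  as.integer(best)
}

#' Default discovery-cascade parameters
#'
#' @param min_len minimum transcript length in nt.
#' @param min_exons minimum exon count.
#' @param min_fpkm minimum FPKM (aggregated across samples per `fpkm_agg`).
#' @param max_orf transcripts whose longest ORF is `>= max_orf` nt are
#'   removed.
#' @param min_support minimum sample occurrence OR assembler support.
#' @param fpkm_agg how FPKM is aggregated across samples before thresholding:
#'   `"max"` (default: expressed in at least one sample) or `"mean"`.
#' @param coding_mode `"any"` (default, strictest: remove if any of the three
#'   coding-potential scores is > 0) or `"all"` (remove only if all three
#'   are > 0).
#' @return A named list of parameters.
#' @export
discovery_params <- function(min_len = 200L, min_exons = 2L, min_fpkm = 0.3,
                             max_orf = 360L, min_support = 2L,
                             fpkm_agg = c("max", "mean"),
                             coding_mode = c("any", "all")) {
  list(min_len = as.integer(min_len), min_exons = as.integer(min_exons),
       min_fpkm = min_fpkm, max_orf = as.integer(max_orf),
       min_support = as.integer(min_support),
       fpkm_agg = match.arg(fpkm_agg),
       coding_mode = match.arg(coding_mode))
}

REMOVAL_REASONS <- c("support", "class_code", "length", "exon_count",
                     "expression", "orf", "coding_potential")

#' Run the lncRNA discovery filter cascade
#'
#' Applies, in order: (0) assembly support — keep if seen in `>= min_support`
#' samples OR supported by `>= min_support` assemblers; (1) class code —
#' `"="` transcripts are classified *known* and exit the cascade, only `"u"`
#' (novel intergenic) and `"i"` (novel intronic) continue, everything else is
#' removed; (2) length `>= min_len` and exon count `>= min_exons`;
#' (3) aggregated FPKM `>= min_fpkm`; (4) longest ORF `< max_orf` nt;
#' (5) coding potential — removed if called coding by the three score columns
#' under `coding_mode`. The first failing step is recorded as the removal
#' reason, so statuses partition the input.
#'
#' @param transcripts named list of [transcript_model()] objects with
#'   sequences attached (sequences are required only for transcripts that
#'   reach the ORF step).
#' @param fpkm an [expression_matrix()] or a numeric matrix (features x
#'   samples) of FPKM values containing every transcript that reaches the
#'   expression step.
#' @param scores `data.frame` with `transcript_id`, `cpc_score`,
#'   `plek_score`, `cnci_score`.
#' @param params see [discovery_params()].
#' @return A list with `lncrna_ids` (retained candidate set), `known_ids`,
#'   `report` (per-transcript status/reason table) and `counts` (transcripts
#'   removed per step).
#' @export
run_discovery_cascade <- function(transcripts, fpkm, scores,
                                  params = discovery_params()) {
  if (inherits(fpkm, "expression_matrix")) fpkm <- fpkm$fpkm
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  names(transcripts) <- ids
  status <- stats::setNames(rep("retained_lncRNA", length(ids)), ids)
  reason <- stats::setNames(rep(NA_character_, length(ids)), ids)

  cc <- vapply(transcripts, `[[`, "", "class_code")
  occ <- vapply(transcripts, function(t) t$sample_occurrence, 1L)
  asm <- vapply(transcripts, function(t) t$assembler_support, 1L)
  len <- vapply(transcripts, transcript_length, 1L)
  nex <- vapply(transcripts, function(t) nrow(t$exons), 1L)

  fail_support <- occ < params$min_support & asm < params$min_support
  status[fail_support] <- "removed"; reason[fail_support] <- "support"

  live <- status == "retained_lncRNA"
  is_known <- live & cc == "="
  status[is_known] <- "known"
  bad_class <- live & !is_known & !(cc %in% c("u", "i"))
  status[bad_class] <- "removed"; reason[bad_class] <- "class_code"

  live <- status == "retained_lncRNA"
  short <- live & len < params$min_len
  status[short] <- "removed"; reason[short] <- "length"
  live <- status == "retained_lncRNA"
  mono <- live & nex < params$min_exons
  status[mono] <- "removed"; reason[mono] <- "exon_count"

  live <- which(status == "retained_lncRNA")
  if (length(live) > 0) {
    missing_expr <- setdiff(ids[live], rownames(fpkm))
    if (length(missing_expr) > 0) {
      stopf("transcript(s) missing from the FPKM matrix: %s",
            paste(utils::head(missing_expr, 5), collapse = ", "))
    }
    agg <- switch(params$fpkm_agg,
                  max = apply(fpkm[ids[live], , drop = FALSE], 1, max),
                  mean = rowMeans(fpkm[ids[live], , drop = FALSE]))
    lowexp <- ids[live][agg < params$min_fpkm]
    status[lowexp] <- "removed"; reason[lowexp] <- "expression"
  }

  live <- which(status == "retained_lncRNA")
  if (length(live) > 0) {
    noseq <- ids[live][vapply(transcripts[live],
                              function(t) is.null(t$sequence), TRUE)]
    if (length(noseq) > 0) {
      stopf("transcript(s) reaching the ORF filter lack a sequence: %s",
            paste(utils::head(noseq, 5), collapse = ", "))
    }
    dot_strand <- ids[live][vapply(transcripts[live], `[[`, "", "strand") == "."]
    if (length(dot_strand) > 0) {
      warnf("%d transcript(s) with unknown strand '.'; sequences scanned as sense strand",
            length(dot_strand))
    }
    orf <- vapply(transcripts[live], function(t) find_max_orf(t$sequence), 1L)
    coding_len <- ids[live][orf >= params$max_orf]
    status[coding_len] <- "removed"; reason[coding_len] <- "orf"
  }

  live <- which(status == "retained_lncRNA")
  if (length(live) > 0) {
    need <- c("transcript_id", "cpc_score", "plek_score", "cnci_score")
    if (!all(need %in% names(scores))) {
      stopf("scores table must have columns: %s", paste(need, collapse = ", "))
    }
    missing_sc <- setdiff(ids[live], scores$transcript_id)
    if (length(missing_sc) > 0) {
      stopf("transcript(s) lacking coding-potential scores: %s",
            paste(utils::head(missing_sc, 5), collapse = ", "))
    }
    sc <- scores[match(ids[live], scores$transcript_id), ]
    pos <- cbind(sc$cpc_score > 0, sc$plek_score > 0, sc$cnci_score > 0)
    called_coding <- switch(params$coding_mode,
                            any = rowSums(pos) >= 1L,
                            all = rowSums(pos) == 3L)
    coding <- ids[live][called_coding]
    status[coding] <- "removed"; reason[coding] <- "coding_potential"
  }

  report <- data.frame(transcript_id = ids, status = unname(status),
                       removal_reason = unname(reason),
                       row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(factor(reason[status == "removed"], levels = REMOVAL_REASONS))
  list(lncrna_ids = ids[status == "retained_lncRNA"],
       known_ids = ids[status == "known"],
       report = report,
       counts = c(input = length(ids),
                  known = sum(status == "known"),
                  retained_lncRNA = sum(status == "retained_lncRNA"),
                  as.vector(counts)) |>
         stats::setNames(c("input", "known", "retained_lncRNA",
                           REMOVAL_REASONS)))
}
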
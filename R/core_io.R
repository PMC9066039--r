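# Readers/writers for GTF/FASTA/BED/TSV and the shared in-memory data model.
#
# Coordinate convention: all in-memory coordinates are 1-based inclusive
# (GTF-native). The only conversion point is the BED boundary, where starts
# become 0-based half-open. TSV files are tab-delimited UTF-8; lines starting
# with "#" are comments.

#' Construct a genomic interval table
#'
#' @param chrom character chromosome names.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stopf("interval coordinates must be non-missing integers")
  }
  if (any(df$start < 1L)) stopf("interval start must be >= 1")
  if (any(df$end < df$start)) {
    bad <- which(df$end < df$start)[1]
    stopf("invalid interval: end (%d) < start (%d)", df$end[bad], df$start[bad])
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stopf("strand must be one of '+', '-', '.'")
  }
  invisible(df)
}

#' Construct a transcript model
#'
#' A transcript model carries the genomic span, exon structure, gffcompare
#' class code and assembly-support metadata of one assembled transcript.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param exons `data.frame` with `start`, `end` (1-based inclusive);
#'   must be non-overlapping. Sorted by start internally.
#' @param class_code single character gffcompare class code (`"u"` novel
#'   intergenic, `"i"` novel intronic, `"="` known, ...).
#' @param assembler_support number of assemblers supporting the model.
#' @param sample_occurrence number of samples the model was assembled in.
#' @param sequence optional nucleotide sequence (transcript-oriented); its
#'   length must equal the summed exon length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             class_code = "=", assembler_support = 1L,
                             sample_occurrence = 1L, sequence = NULL) {
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end < exons$start)) {
    stopf("transcript %s: exon end < start", transcript_id)
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stopf("transcript %s: overlapping exons", transcript_id)
  }
  len <- sum(exons$end - exons$start + 1L)
  if (!is.null(sequence)) {
    if (nchar(sequence) != len) {
      stopf("transcript %s: sequence length %d != exonic length %d",
            transcript_id, nchar(sequence), len)
    }
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 start = min(exons$start),
                 end = max(exons$end),
                 strand = as.character(strand),
                 exons = exons,
                 class_code = as.character(class_code),
                 assembler_support = as.integer(assembler_support),
                 sample_occurrence = as.integer(sample_occurrence),
                 sequence = sequence),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s) class '%s', %d exon(s), %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              x$class_code, nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' Exonic length of a transcript model
#' @param x a `transcript_model`.
#' @return Integer summed exon length in nt.
#' @export
transcript_length <- function(x) {
  sum(x$exons$end - x$exons$start + 1L)
}

parse_gtf_attributes <- function(attr_str) {
  # 'key "value"; key2 "value2";' -> named character vector
  m <- gregexpr("(\\w+)\\s+\"([^\"]*)\"", attr_str, perl = TRUE)
  pieces <- regmatches(attr_str, m)[[1]]
  if (length(pieces) == 0) return(character(0))
  keys <- sub("^(\\w+)\\s+.*$", "\\1", pieces)
  vals <- sub("^\\w+\\s+\"([^\"]*)\"$", "\\1", pieces)
  stats::setNames(vals, keys)
}

#' Read transcript models from a GTF file
#'
#' Expects gffcompare-style attributes: `transcript_id`, `gene_id` and
#' optionally `class_code`, `assembler_support`, `sample_occurrence`. Exon
#' rows are aggregated per transcript and sorted by start. A transcript with
#' no `class_code` attribute defaults to `"="` with a warning.
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model()] objects (names = transcript id).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stopf("malformed GTF line %d in %s: expected 9 tab-separated fields, got %d",
          idx[bad], path, nf[bad])
  }
  feat <- vapply(fields, `[[`, "", 3L)
  exon_rows <- which(feat == "exon")
  if (length(exon_rows) == 0) stopf("no exon records in %s", path)

  attrs <- lapply(fields, function(f) parse_gtf_attributes(f[9]))
  tid <- vapply(attrs, function(a) {
    if (!"transcript_id" %in% names(a)) NA_character_ else a[["transcript_id"]]
  }, "")
  if (anyNA(tid[exon_rows])) {
    stopf("GTF line %d lacks a transcript_id attribute",
          idx[which(is.na(tid) & feat == "exon")[1]])
  }

  starts <- as.integer(vapply(fields, `[[`, "", 4L))
  ends <- as.integer(vapply(fields, `[[`, "", 5L))
  if (any(ends[exon_rows] < starts[exon_rows])) {
    bad <- exon_rows[which(ends[exon_rows] < starts[exon_rows])[1]]
    stopf("GTF line %d: end (%d) < start (%d)", idx[bad], ends[bad], starts[bad])
  }

  ord <- split(exon_rows, factor(tid[exon_rows], levels = unique(tid[exon_rows])))
  missing_cc <- character(0)
  models <- lapply(ord, function(rows) {
    r1 <- rows[1]
    a <- attrs[[r1]]
    # transcript-level attributes may live on a 'transcript' row instead
    trow <- which(feat == "transcript" & tid == tid[r1])
    if (length(trow) > 0) a <- c(attrs[[trow[1]]], a)
    cc <- if ("class_code" %in% names(a)) a[["class_code"]] else {
      missing_cc <<- c(missing_cc, tid[r1])
      "="
    }
    transcript_model(
      transcript_id = tid[r1],
      gene_id = if ("gene_id" %in% names(a)) a[["gene_id"]] else tid[r1],
      chrom = fields[[r1]][1],
      strand = fields[[r1]][7],
      exons = data.frame(start = starts[rows], end = ends[rows]),
      class_code = cc,
      assembler_support = if ("assembler_support" %in% names(a))
        as.integer(a[["assembler_support"]]) else 1L,
      sample_occurrence = if ("sample_occurrence" %in% names(a))
        as.integer(a[["sample_occurrence"]]) else 1L)
  })
  if (length(missing_cc) > 0) {
    warnf("%d transcript(s) lack a class_code attribute; defaulting to '=' (%s%s)",
          length(missing_cc), paste(utils::head(missing_cc, 3), collapse = ", "),
          if (length(missing_cc) > 3) ", ..." else "")
  }
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  models
}

#' Write transcript models to GTF
#'
#' Inverse of [read_gtf()]: emits one `transcript` row plus one `exon` row per
#' exon, with `class_code`, `assembler_support` and `sample_occurrence`
#' attributes, so that a write/read round trip is lossless for every field the
#' model stores (except the sequence, which lives in FASTA).
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tx in transcripts) {
    attr_str <- sprintf(
      'transcript_id "%s"; gene_id "%s"; class_code "%s"; assembler_support "%d"; sample_occurrence "%d";',
      tx$transcript_id, tx$gene_id, tx$class_code, tx$assembler_support,
      tx$sample_occurrence)
    writeLines(sprintf("%s\tlactnet\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, tx$start, tx$end, tx$strand, attr_str), con)
    writeLines(sprintf("%s\tlactnet\texon\t%d\t%d\t.\t%s\t.\t%s",
                       tx$chrom, tx$exons$start, tx$exons$end, tx$strand,
                       attr_str), con)
  }
  invisible(path)
}

#' Read transcript sequences from FASTA
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Attach FASTA sequences to transcript models
#'
#' @param transcripts named list of transcript models.
#' @param seqs named character vector of sequences (transcript ids as names).
#' @param strict error if a sequence length mismatches the exonic length.
#' @return The transcript list with `$sequence` filled where available.
#' @export
attach_sequences <- function(transcripts, seqs, strict = TRUE) {
  for (id in names(transcripts)) {
    if (id %in% names(seqs)) {
      len <- transcript_length(transcripts[[id]])
      if (nchar(seqs[[id]]) != len) {
        msg <- sprintf("transcript %s: sequence length %d != exonic length %d",
                       id, nchar(seqs[[id]]), len)
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
      transcripts[[id]]$sequence <- unname(seqs[[id]])
    }
  }
  transcripts
}

#' Transcript loci as an interval table
#'
#' @param transcripts list of transcript models.
#' @return `data.frame` with `feature_id`, `chrom`, `start`, `end`, `strand`.
#' @export
transcript_loci <- function(transcripts) {
  data.frame(
    feature_id = vapply(transcripts, `[[`, "", "transcript_id"),
    chrom = vapply(transcripts, `[[`, "", "chrom"),
    start = vapply(transcripts, function(t) t$start, 1L),
    end = vapply(transcripts, function(t) t$end, 1L),
    strand = vapply(transcripts, `[[`, "", "strand"),
    row.names = NULL, stringsAsFactors = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Construct an expression matrix object
#'
#' Bundles a counts layer, an FPKM layer and the sample design
#' (individual, stage) with consistent dimensions and sample order.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param fpkm non-negative finite matrix of identical shape (FPKM units).
#' @param design `data.frame` with `sample_id`, `individual`, `stage`; one row
#'   per column of `counts`, `(individual, stage)` pairs unique.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, fpkm, design) {
  counts <- as.matrix(counts)
  fpkm <- as.matrix(fpkm)
  if (!identical(dim(counts), dim(fpkm))) {
    stopf("counts (%d x %d) and fpkm (%d x %d) dimensions differ",
          nrow(counts), ncol(counts), nrow(fpkm), ncol(fpkm))
  }
  if (ncol(counts) != nrow(design)) {
    stopf("design has %d rows but matrices have %d columns",
          nrow(design), ncol(counts))
  }
  if (!identical(colnames(counts), design$sample_id)) {
    stopf("counts column names must equal design$sample_id in order")
  }
  if (any(counts < 0)) stopf("negative counts are not allowed")
  if (any(abs(counts - round(counts)) > 1e-6)) {
    stopf("counts must be integers")
  }
  if (any(!is.finite(fpkm)) || any(fpkm < 0)) {
    stopf("FPKM values must be finite and non-negative")
  }
  design$stage <- as_stage(design$stage)
  design$individual <- factor(design$individual)
  if (anyDuplicated(design[, c("individual", "stage")])) {
    stopf("(individual, stage) pairs in the design must be unique")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, fpkm = fpkm, design = design),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (%d individuals, %d stages)\n",
              nrow(x$counts), ncol(x$counts),
              nlevels(x$design$individual),
              length(unique(x$design$stage))))
  invisible(x)
}

#' Read counts + FPKM + design TSVs into an expression matrix
#'
#' Both matrices have a `feature_id` first column and one column per sample;
#' columns are realigned to the design-table sample order, so the two layers
#' always share one sample ordering regardless of on-disk column order.
#'
#' @param counts_path,fpkm_path,design_path TSV paths.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(counts_path, fpkm_path, design_path) {
  design <- read_tsv(design_path)
  need <- c("sample_id", "individual", "stage")
  if (!all(need %in% names(design))) {
    stopf("design table must have columns: %s", paste(need, collapse = ", "))
  }
  load_layer <- function(path) {
    df <- read_tsv(path)
    if (names(df)[1] != "feature_id") {
      stopf("%s: first column must be 'feature_id'", path)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$feature_id
    missing <- setdiff(design$sample_id, colnames(m))
    extra <- setdiff(colnames(m), design$sample_id)
    if (length(missing) > 0) {
      stopf("%s: sample(s) in design but not in matrix: %s",
            path, paste(missing, collapse = ", "))
    }
    if (length(extra) > 0) {
      stopf("%s: sample(s) in matrix but not in design: %s",
            path, paste(extra, collapse = ", "))
    }
    m[, design$sample_id, drop = FALSE]
  }
  counts <- load_layer(counts_path)
  fpkm <- load_layer(fpkm_path)
  if (!identical(rownames(counts), rownames(fpkm))) {
    stopf("counts and fpkm feature_id columns differ")
  }
  expression_matrix(round(counts), fpkm, design)
}

#' Write an expression matrix to counts/FPKM/design TSVs
#' @param expr an [expression_matrix()].
#' @param counts_path,fpkm_path,design_path output TSV paths.
#' @return Invisibly, the three paths.
#' @export
write_expression_matrix <- function(expr, counts_path, fpkm_path, design_path) {
  dump_layer <- function(m, path) {
    write_tsv(data.frame(feature_id = rownames(m), m, check.names = FALSE),
              path)
  }
  dump_layer(expr$counts, counts_path)
  dump_layer(expr$fpkm, fpkm_path)
  d <- expr$design
  d$stage <- as.character(d$stage)
  d$individual <- as.character(d$individual)
  write_tsv(d, design_path)
  invisible(c(counts_path, fpkm_path, design_path))
}

#' Read a SNP effect table
#'
#' TSV with columns `id`, `chrom`, `pos`, `beta` and optionally genotype
#' counts `n_AA`, `n_Aa`, `n_aa`. Records are returned sorted by
#' (chrom, pos); duplicate ids and non-numeric effects are rejected.
#'
#' @param path TSV path.
#' @return `data.frame` of SNP records in coordinate order.
#' @export
read_snp_effects <- function(path) {
  df <- read_tsv(path, colClasses = NA)
  need <- c("id", "chrom", "pos", "beta")
  if (!all(need %in% names(df))) {
    stopf("SNP table must have columns: %s", paste(need, collapse = ", "))
  }
  beta_num <- suppressWarnings(as.numeric(df$beta))
  bad <- which(is.na(beta_num) | !is.finite(beta_num))
  if (length(bad) > 0) {
    stopf("non-numeric beta at row %d (id %s)", bad[1], df$id[bad[1]])
  }
  df$beta <- beta_num
  df$pos <- as.integer(df$pos)
  if (any(df$pos < 1L)) stopf("SNP pos must be >= 1")
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    stopf("duplicate SNP id(s): %s", paste(unique(dup), collapse = ", "))
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a SNP effect table
#' @param snps `data.frame` as returned by [read_snp_effects()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_effects <- function(snps, path) {
  write_tsv(snps, path)
}

#' Write named intervals as BED6
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention (`start - 1`, `end`). Rows are ordered by
#' (chrom, start) for deterministic output.
#'
#' @param features `data.frame` with `feature_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (default `"."`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  if (nrow(features) == 0) {
    file.create(path)
    return(invisible(path))
  }
  validate_intervals(data.frame(chrom = features$chrom, start = features$start,
                                end = features$end,
                                strand = if ("strand" %in% names(features))
                                  features$strand else "."))
  strand <- if ("strand" %in% names(features)) features$strand else
    rep(".", nrow(features))
  ord <- order(features$chrom, features$start)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   features$chrom[ord], features$start[ord] - 1L,
                   features$end[ord], features$feature_id[ord], strand[ord])
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file back to 1-based inclusive intervals
#' @param path BED file path.
#' @return `data.frame` with `feature_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(feature_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) {
    stopf("BED line %d: expected 6 fields", which(lengths(fields) < 6L)[1])
  }
  data.frame(
    feature_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)) + 1L,
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    strand = vapply(fields, `[[`, "", 6L),
    stringsAsFactors = FALSE)
}
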
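#' @title Readers and writers for the pipeline's external formats
#' @description Every external format the pipeline touches has one strict
#'   reader and (where round-tripping is needed) one writer. Readers validate
#'   aggressively and report file/line context; writers emit UTF-8 TSV with
#'   `#`-prefixed metadata header lines so a written table carries its own
#'   provenance.
#' @name data-io
#' @keywords internal
NULL

read_tsv_body <- function(path, required, what = "table", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop(path, ": empty ", what, call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

check_numeric_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  num <- suppressWarnings(as.numeric(raw))
  bad <- is.na(num) & !(allow_na & (is.na(raw) | raw %in% c("NA", "")))
  if (any(bad)) {
    stop(path, ": non-numeric value in column '", col, "' at data row ",
         which(bad)[1], " ('", raw[which(bad)[1]], "')", call. = FALSE)
  }
  num
}

write_meta_header <- function(con, meta) {
  for (nm in names(meta)) {
    writeLines(sprintf("# %s=%s", nm, paste(meta[[nm]], collapse = ",")), con)
  }
}

#' Read a differential-expression result TSV
#'
#' Expects a DESeq2-style results table with columns `gene_id`, `biotype`,
#' `base_mean`, `log2fc`, `pvalue`, `padj`. Rows with missing `padj` are
#' retained (and later treated as not significant, the DESeq2 independent-
#' filtering convention).
#'
#' @param path TSV file; lines starting with `#` are metadata and skipped.
#' @param dataset_id,species,tissue,assay dataset metadata (see [de_table()]).
#' @return A [de_table()].
#' @export
read_de_table <- function(path, dataset_id, species, tissue, assay) {
  req <- c("gene_id", "biotype", "base_mean", "log2fc", "pvalue", "padj")
  df <- read_tsv_body(path, req, "DE table")
  for (col in c("base_mean", "log2fc", "pvalue")) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  df$padj <- check_numeric_col(df, "padj", path, allow_na = TRUE)
  de_table(df[req], dataset_id = dataset_id, species = species,
           tissue = tissue, assay = assay)
}

#' Write a differential-expression table to TSV
#'
#' @param x a [de_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  stopifnot(inherits(x, "de_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_header(con, list(dataset_id = x$dataset_id, species = x$species,
                              tissue = x$tissue, assay = x$assay))
  utils::write.table(x$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene loci from a GTF file
#'
#' Keeps gene-level features only; coordinates stay in GTF convention
#' (1-based, inclusive). `expressed` is set from membership in
#' `expressed_ids`.
#'
#' @param path GTF file with gene features carrying `gene_id` and
#'   `gene_biotype` attributes.
#' @param expressed_ids character vector of expressed gene ids.
#' @return A [gene_loci()] data.frame.
#' @export
read_gtf_loci <- function(path, expressed_ids = character()) {
  gr <- rtracklayer::import(path, format = "gtf")
  types <- as.character(gr$type)
  genes <- gr[types == "gene"]
  if (!length(genes)) {
    warning(path, ": no gene-level features found; returning empty locus set",
            call. = FALSE)
    return(gene_loci(data.frame(gene_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character(), biotype = character(),
                                expressed = logical())))
  }
  ids <- genes$gene_id
  if (is.null(ids) || any(is.na(ids) | ids == "")) {
    bad <- if (is.null(ids)) 1L else which(is.na(ids) | ids == "")[1]
    stop(path, ": gene feature #", bad, " missing gene_id attribute",
         call. = FALSE)
  }
  biotype <- genes$gene_biotype
  if (is.null(biotype)) biotype <- rep("other", length(genes))
  suppressWarnings(gene_loci(data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(genes))),
    biotype = as.character(biotype),
    expressed = as.character(ids) %in% expressed_ids)))
}

#' Write gene loci as GTF
#'
#' @param loci a [gene_loci()] data.frame.
#' @param path output GTF file.
#' @return `path`, invisibly.
#' @export
write_gtf_loci <- function(loci, path) {
  bt <- c(pcg = "protein_coding", lncrna = "lncRNA", mirna = "miRNA",
          other = "misc_RNA")[loci$biotype]
  lines <- sprintf(
    '%s\tucsig\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    loci$chrom, loci$start, loci$end,
    ifelse(loci$strand == ".", "+", loci$strand), loci$gene_id, bt)
  writeLines(lines, path)
  invisible(path)
}

#' Read risk-locus intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the internal 1-based
#' inclusive convention at this boundary. Zero-length (point) BED records are
#' accepted and become 1-bp intervals.
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return data.frame with `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
read_bed_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = pmax(GenomicRanges::end(gr), GenomicRanges::start(gr)),
    name = if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("locus_%d", seq_along(gr)),
    stringsAsFactors = FALSE)
}

#' Read a STRING-dialect edge list
#'
#' Expects columns `protein1`, `protein2`, `combined_score` with scores on
#' STRING's 0-1000 scale. Scores are divided by 1000, edges below
#' `min_confidence` are dropped, and symmetric duplicates are collapsed
#' keeping the maximum confidence.
#'
#' @param path edge TSV.
#' @param min_confidence confidence cutoff on the 0-1 scale; the default 0.4
#'   is STRING's "medium confidence".
#' @return A [gene_network()].
#' @export
read_string_edges <- function(path, min_confidence = 0.4) {
  df <- read_tsv_body(path, c("protein1", "protein2", "combined_score"),
                      "edge list")
  score <- check_numeric_col(df, "combined_score", path)
  if (any(score < 0 | score > 1000)) {
    stop(path, ": combined_score outside [0,1000] at data row ",
         which(score < 0 | score > 1000)[1], call. = FALSE)
  }
  conf <- score / 1000
  keep <- conf >= min_confidence
  gene_network(data.frame(a = df$protein1[keep], b = df$protein2[keep],
                          confidence = conf[keep]))
}

#' Write a network as a STRING-dialect edge TSV
#'
#' @param net a [gene_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_header(con, list(n_nodes = length(net$nodes)))
  out <- data.frame(protein1 = net$edges$a, protein2 = net$edges$b,
                    combined_score = as.integer(round(net$edges$confidence * 1000)))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mouse/human orthology TSV
#'
#' @param path TSV with columns `mouse_gene_id`, `human_gene_id`, `relation`.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path) {
  df <- read_tsv_body(path, c("mouse_gene_id", "human_gene_id", "relation"),
                      "orthology map")
  orthology_map(df)
}

#' Write an orthology map to TSV
#' @param x an [orthology_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orthology <- function(x, path) {
  stopifnot(inherits(x, "orthology_map"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_header(con, list(n_pairs = nrow(x$pairs)))
  utils::write.table(x$pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, tab-separated `id`, `description`,
#' members. The description column is kept as the term name.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop(path, ": line ", short[1],
         ": GMT records need id, description and >= 1 member", call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate term id '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, stats::setNames(vapply(parts, `[[`, "", 2L), ids))
}

#' Write a gene-set collection as GMT
#' @param x a [gene_set_collection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$term_names[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct CSV
#'
#' @param path CSV with columns `sample_id`, `group`, `tissue`, `gene_id`,
#'   `ct` (one row per technical replicate).
#' @return A [ct_table()].
#' @export
read_ct_csv <- function(path) {
  df <- read_tsv_body(path, c("sample_id", "group", "tissue", "gene_id", "ct"),
                      "Ct table", sep = ",")
  df$ct <- check_numeric_col(df, "ct", path)
  ct_table(df)
}

#' Write a Ct table as CSV
#' @param x a [ct_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  utils::write.table(x$rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-to-target mapping TSV
#'
#' @param path TSV with columns `mirna_id`, `target_gene_id`; one row per
#'   (miRNA, target) pair.
#' @return named list: miRNA id -> character vector of target gene ids.
#' @export
read_target_map <- function(path) {
  df <- read_tsv_body(path, c("mirna_id", "target_gene_id"), "target map")
  split(as.character(df$target_gene_id), as.character(df$mirna_id))
}

#' Write a miRNA-to-target mapping TSV
#' @param x named list of target id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(x, path) {
  df <- data.frame(mirna_id = rep(names(x), lengths(x)),
                   target_gene_id = unlist(x, use.names = FALSE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_header(con, list(n_mirnas = length(x)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an SDE set to TSV
#'
#' Entries first, then the inconsistent partition with direction
#' `inconsistent`; the `#` header records provenance and thresholds.
#'
#' @param x an [sde_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sde_set <- function(x, path) {
  stopifnot(inherits(x, "sde_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(list(species = x$species, tissue = x$tissue, source = x$source),
            x$thresholds)
  write_meta_header(con, meta)
  ent <- x$entries
  if (length(x$inconsistent)) {
    inc <- ent[0, , drop = FALSE]
    inc[seq_along(x$inconsistent), "gene_id"] <- x$inconsistent
    inc$direction <- "inconsistent"
    ent <- rbind(ent, inc)
  }
  utils::write.table(ent, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
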
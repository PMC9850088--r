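#' @title Core domain types
#' @description Lightweight S3 containers shared by every stage of the
#'   pipeline. All constructors validate their invariants and fail loudly;
#'   downstream code can therefore assume well-formed objects.
#' @name ucsig-types
#' @keywords internal
NULL

BIOTYPES <- c("pcg", "lncrna", "mirna", "other")
SPECIES <- c("mouse", "human")
TISSUES <- c("colon", "blood")
ASSAYS <- c("total_rna", "small_rna")

#' Construct a differential-expression table
#'
#' A `de_table` holds one dataset's per-gene differential-expression
#' statistics (a DESeq2-style results table) together with its metadata:
#' which dataset, species, tissue and assay it came from.
#'
#' @param records data.frame with columns `gene_id`, `biotype`, `base_mean`,
#'   `log2fc`, `pvalue`, `padj`. `padj` may be `NA` (genes filtered by the
#'   upstream DE tool); such genes are never treated as significant.
#' @param dataset_id character scalar identifying the dataset.
#' @param species `"mouse"` or `"human"`.
#' @param tissue `"colon"` or `"blood"`.
#' @param assay `"total_rna"` or `"small_rna"`.
#' @return An object of class `de_table`.
#' @export
de_table <- function(records, dataset_id, species, tissue, assay) {
  species <- match.arg(species, SPECIES)
  tissue <- match.arg(tissue, TISSUES)
  assay <- match.arg(assay, ASSAYS)
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  req <- c("gene_id", "biotype", "base_mean", "log2fc", "pvalue", "padj")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("de_table records missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[req]
  records$gene_id <- as.character(records$gene_id)
  records$biotype <- normalize_biotype(records$biotype)
  dup <- records$gene_id[duplicated(records$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id in de_table '", dataset_id, "': first duplicate '",
         dup[1], "'", call. = FALSE)
  }
  for (col in c("base_mean", "log2fc", "pvalue", "padj")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if (any(!is.finite(records$log2fc))) {
    stop("non-finite log2fc in de_table '", dataset_id, "'", call. = FALSE)
  }
  if (any(records$base_mean < 0, na.rm = TRUE)) {
    stop("negative base_mean in de_table '", dataset_id, "'", call. = FALSE)
  }
  bad_p <- records$pvalue < 0 | records$pvalue > 1 |
    (!is.na(records$padj) & (records$padj < 0 | records$padj > 1))
  if (any(bad_p, na.rm = TRUE)) {
    stop("p-values outside [0,1] in de_table '", dataset_id, "'", call. = FALSE)
  }
  structure(
    list(dataset_id = dataset_id, species = species, tissue = tissue,
         assay = assay, records = records),
    class = "de_table")
}

#' Map free-text biotype labels onto the closed vocabulary
#'
#' Recognised labels (case-insensitive) map onto `pcg`, `lncrna`, `mirna`;
#' anything else becomes `other` with a one-shot warning, mirroring the usual
#' "pseudogene / TEC / snoRNA / miscRNA" catch-all category.
#'
#' @param x character vector of biotype labels.
#' @return character vector over `c("pcg", "lncrna", "mirna", "other")`.
#' @export
normalize_biotype <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("other", length(x))
  out[x %in% c("pcg", "protein_coding")] <- "pcg"
  out[x %in% c("lncrna", "lincrna", "antisense", "long_noncoding")] <- "lncrna"
  out[x %in% c("mirna")] <- "mirna"
  unknown <- setdiff(unique(x[out == "other"]), "other")
  if (length(unknown)) {
    warning("unrecognised biotype label(s) mapped to 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("<de_table> %s  %s/%s/%s  %d genes\n", x$dataset_id, x$species,
              x$tissue, x$assay, nrow(x$records)))
  invisible(x)
}

#' Construct a set of significantly differentially expressed genes
#'
#' Direction-labelled significant genes for one (species, tissue), from a
#' single dataset or from a multi-dataset combination. Combined sets carry an
#' `inconsistent` partition: genes significant in enough datasets but with
#' conflicting fold-change signs, which are excluded from `entries`.
#'
#' @param entries data.frame with at least `gene_id`, `biotype`, `direction`
#'   (`"up"`/`"down"`); combined sets additionally carry `support` and
#'   `signs`.
#' @param inconsistent character vector of gene ids (empty for
#'   single-dataset sets).
#' @param species,tissue,source provenance; `source` is a dataset id or
#'   `"combined"`.
#' @param thresholds named list recording the thresholds used.
#' @return An object of class `sde_set`.
#' @export
sde_set <- function(entries, inconsistent = character(), species, tissue,
                    source, thresholds = list()) {
  species <- match.arg(species, SPECIES)
  tissue <- match.arg(tissue, TISSUES)
  entries <- as.data.frame(entries)
  stopifnot(all(c("gene_id", "direction") %in% names(entries)))
  if (nrow(entries) && !all(entries$direction %in% c("up", "down"))) {
    stop("sde_set directions must be 'up' or 'down'", call. = FALSE)
  }
  if (anyDuplicated(entries$gene_id)) {
    stop("duplicate gene_id in sde_set entries", call. = FALSE)
  }
  overlap <- intersect(entries$gene_id, inconsistent)
  if (length(overlap)) {
    stop("genes present in both entries and inconsistent partition: ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  structure(
    list(species = species, tissue = tissue, source = source,
         entries = entries, inconsistent = as.character(inconsistent),
         thresholds = thresholds),
    class = "sde_set")
}

#' @export
print.sde_set <- function(x, ...) {
  cat(sprintf("<sde_set> %s/%s [%s]  %d genes (%d up, %d down), %d inconsistent\n",
              x$species, x$tissue, x$source, nrow(x$entries),
              sum(x$entries$direction == "up"),
              sum(x$entries$direction == "down"),
              length(x$inconsistent)))
  invisible(x)
}

#' Construct an orthology map
#'
#' Mouse/human gene pairs with their relationship class. One-to-one pairs
#' must be exclusive: each member of a `one2one` pair appears in exactly one
#' pair of the map.
#'
#' @param pairs data.frame with columns `mouse_gene_id`, `human_gene_id`,
#'   `relation` (`"one2one"` or `"one2many"`).
#' @return An object of class `orthology_map`.
#' @export
orthology_map <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("mouse_gene_id", "human_gene_id", "relation") %in% names(pairs)))
  pairs$mouse_gene_id <- as.character(pairs$mouse_gene_id)
  pairs$human_gene_id <- as.character(pairs$human_gene_id)
  bad <- setdiff(unique(pairs$relation), c("one2one", "one2many"))
  if (length(bad)) {
    stop("unknown orthology relation label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(pairs$mouse_gene_id, pairs$human_gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate orthology pair: ", key[duplicated(key)][1], call. = FALSE)
  }
  o2o <- pairs[pairs$relation == "one2one", , drop = FALSE]
  viol <- c(
    intersect(o2o$mouse_gene_id,
              pairs$mouse_gene_id[duplicated(pairs$mouse_gene_id) |
                                    duplicated(pairs$mouse_gene_id, fromLast = TRUE)]),
    intersect(o2o$human_gene_id,
              pairs$human_gene_id[duplicated(pairs$human_gene_id) |
                                    duplicated(pairs$human_gene_id, fromLast = TRUE)]))
  if (length(viol)) {
    stop("one2one pair member(s) appear in multiple pairs: ",
         paste(utils::head(unique(viol), 3), collapse = ", "), call. = FALSE)
  }
  structure(list(pairs = pairs), class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("<orthology_map> %d pairs (%d one2one, %d one2many)\n",
              nrow(x$pairs), sum(x$pairs$relation == "one2one"),
              sum(x$pairs$relation == "one2many")))
  invisible(x)
}

#' Construct an undirected confidence-scored gene network
#'
#' @param edges data.frame with columns `a`, `b`, `confidence` in `[0,1]`.
#'   Self-loops are rejected; symmetric duplicates are collapsed keeping the
#'   maximum confidence.
#' @param nodes optional character vector of node ids; defaults to the edge
#'   endpoints. Extra ids give isolated nodes.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("a", "b", "confidence") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$confidence <- as.numeric(edges$confidence)
  if (any(edges$a == edges$b)) {
    stop("self-loop edge(s) not allowed", call. = FALSE)
  }
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidence outside [0,1]", call. = FALSE)
  }
  # canonical orientation, then collapse duplicates keeping max confidence
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  edges$a <- lo
  edges$b <- hi
  if (nrow(edges)) {
    key <- paste(edges$a, edges$b, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$confidence <- as.numeric(conf[paste(edges$a, edges$b, sep = "\r")])
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(nodes, edges$a, edges$b)))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' A carrier for KEGG/GO-style term collections: each term has an id, a
#' human-readable name, and a non-empty member list.
#'
#' @param sets named list of character vectors (names are term ids).
#' @param term_names optional named character vector of display names keyed
#'   by term id; defaults to the ids themselves.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, term_names = NULL) {
  stopifnot(is.list(sets))
  if (length(sets)) {
    stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
    if (any(lengths(sets) == 0)) {
      stop("gene sets must be non-empty", call. = FALSE)
    }
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, term_names = term_names),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms, median size %s\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else "NA"))
  invisible(x)
}

#' Construct a qPCR Ct table
#'
#' Long-format Ct measurements: one row per technical replicate of one gene
#' in one sample.
#'
#' @param rows data.frame with columns `sample_id`, `group`
#'   (`"case"`/`"control"`), `tissue`, `gene_id`, `ct`.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(rows) {
  rows <- as.data.frame(rows)
  req <- c("sample_id", "group", "tissue", "gene_id", "ct")
  stopifnot(all(req %in% names(rows)))
  rows <- rows[req]
  rows$ct <- as.numeric(rows$ct)
  if (any(!is.finite(rows$ct)) || any(rows$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  if (!all(rows$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'", call. = FALSE)
  }
  structure(list(rows = rows), class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table> %d measurements, %d samples, %d genes\n",
              nrow(x$rows), length(unique(x$rows$sample_id)),
              length(unique(x$rows$gene_id))))
  invisible(x)
}

#' Construct a gene-locus table
#'
#' Gene coordinates in the internal convention: 1-based, fully inclusive
#' (the GTF convention). BED inputs are converted at the read boundary.
#'
#' @param loci data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `expressed`.
#' @return An object of class `gene_loci` (a validated data.frame).
#' @export
gene_loci <- function(loci) {
  loci <- as.data.frame(loci)
  req <- c("gene_id", "chrom", "start", "end", "strand", "biotype", "expressed")
  stopifnot(all(req %in% names(loci)))
  loci <- loci[req]
  loci$gene_id <- as.character(loci$gene_id)
  loci$start <- as.integer(loci$start)
  loci$end <- as.integer(loci$end)
  if (any(loci$start < 1) || any(loci$end < loci$start)) {
    stop("locus coordinates must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!all(loci$strand %in% c("+", "-", "."))) {
    stop("strand must be '+', '-' or '.'", call. = FALSE)
  }
  loci$biotype <- normalize_biotype(loci$biotype)
  loci$expressed <- as.logical(loci$expressed)
  class(loci) <- c("gene_loci", "data.frame")
  loci
}
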
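# small builders used across test files

mk_records <- function(gene_id, log2fc, padj, biotype = "pcg",
                       base_mean = 100, pvalue = NULL) {
  data.frame(gene_id = gene_id, biotype = biotype, base_mean = base_mean,
             log2fc = log2fc,
             pvalue = if (is.null(pvalue)) pmin(ifelse(is.na(padj), 0.5,
                                                       padj), 1) else pvalue,
             padj = padj, stringsAsFactors = FALSE)
}

mk_de <- function(gene_id, log2fc, padj, biotype = "pcg",
                  dataset_id = "d1", species = "human", tissue = "colon",
                  assay = "total_rna") {
  de_table(mk_records(gene_id, log2fc, padj, biotype),
           dataset_id, species, tissue, assay)
}

mk_loci <- function(gene_id, chrom, start, end, biotype = "pcg",
                    expressed = TRUE, strand = "+") {
  gene_loci(data.frame(gene_id = gene_id, chrom = chrom, start = start,
                       end = end, strand = strand, biotype = biotype,
                       expressed = expressed, stringsAsFactors = FALSE))
}

mk_sde <- function(gene_id, direction, species = "human", tissue = "colon",
                   biotype = "pcg", inconsistent = character(),
                   source = "test") {
  sde_set(data.frame(gene_id = gene_id,
                     biotype = rep_len(biotype, length(gene_id)),
                     direction = rep_len(direction, length(gene_id)),
                     stringsAsFactors = FALSE),
          inconsistent, species = species, tissue = tissue, source = source)
}

mk_orth <- function(mouse, human, relation = "one2one") {
  orthology_map(data.frame(mouse_gene_id = mouse, human_gene_id = human,
                           relation = relation, stringsAsFactors = FALSE))
}
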
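test_that("well-formed DE TSV parses and malformed ones fail with context", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tbase_mean\tlog2fc\tpvalue\tpadj",
               "G1\tpcg\t100\t1.5\t0.001\t0.01",
               "G2\tlncrna\t50\t-2.1\t0.002\t0.02",
               "G3\tpcg\t10\t0.3\t0.5\tNA"), path)
  t <- read_de_table(path, "d1", "human", "colon", "total_rna")
  expect_s3_class(t, "de_table")
  expect_equal(nrow(t$records), 3)
  expect_true(is.na(t$records$padj[3]))

  # missing column named in the error
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tbase_mean\tlog2fc\tpvalue",
               "G1\tpcg\t100\t1.5\t0.001"), p2)
  expect_error(read_de_table(p2, "d1", "human", "colon", "total_rna"), "padj")

  # duplicate gene id reported
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tbase_mean\tlog2fc\tpvalue\tpadj",
               "G1\tpcg\t100\t1.5\t0.001\t0.01",
               "G1\tpcg\t10\t0.3\t0.5\t0.9"), p3)
  expect_error(read_de_table(p3, "d1", "human", "colon", "total_rna"), "G1")

  # non-numeric statistic reported with its row
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tbiotype\tbase_mean\tlog2fc\tpvalue\tpadj",
               "G1\tpcg\t100\toops\t0.001\t0.01"), p4)
  expect_error(read_de_table(p4, "d1", "human", "colon", "total_rna"),
               "log2fc.*row 1")
})

test_that("DE table round-trips through write/read including synthetic output", {
  gen <- synth_de(synth_de_config(n_null = 200, tissues = "colon"), seed = 7)
  t <- gen$tables[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(t, path)
  t2 <- read_de_table(path, t$dataset_id, t$species, t$tissue, t$assay)
  expect_equal(t2$records$gene_id, t$records$gene_id)
  expect_equal(t2$records$log2fc, t$records$log2fc, tolerance = 1e-12)
  expect_equal(t2$records$padj, t$records$padj, tolerance = 1e-12)
  expect_equal(t2$records$biotype, t$records$biotype)
})

test_that("GTF loci reader preserves 1-based coordinates and flags expression", {
  loci <- mk_loci(c("A", "B", "L1"), "chr1", c(100, 5000, 9000),
                  c(200, 6000, 9500), biotype = c("pcg", "pcg", "lncrna"))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_loci(loci, path)
  got <- read_gtf_loci(path, expressed_ids = c("A", "L1"))
  expect_equal(got$gene_id, c("A", "B", "L1"))
  expect_equal(got$start, c(100L, 5000L, 9000L))
  expect_equal(got$end, c(200L, 6000L, 9500L))
  expect_equal(got$biotype, c("pcg", "pcg", "lncrna"))
  expect_equal(got$expressed, c(TRUE, FALSE, TRUE))
})

test_that("GTF without gene features yields empty loci with a warning", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\tsrc\ttranscript\t100\t200\t.\t+\t.\t",
                    'gene_id "G1"; transcript_id "T1";'), path)
  expect_warning(got <- read_gtf_loci(path), "no gene-level features")
  expect_equal(nrow(got), 0)
})

test_that("synthetic GTF of 50 genes yields 50 valid loci", {
  sl <- synth_loci(50, seed = 3)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_loci(sl$loci, path)
  got <- read_gtf_loci(path, expressed_ids = sl$loci$gene_id)
  expect_equal(nrow(got), 50)
  expect_true(all(got$start >= 1))
  expect_true(all(got$start <= got$end))
  expect_setequal(got$gene_id, sl$loci$gene_id)
})

test_that("STRING reader rescales, thresholds, and collapses symmetric dupes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t900", "B\tA\t850"), path)
  net <- read_string_edges(path, min_confidence = 0.4)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$confidence, 0.9)

  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB\t150"), p2)
  net2 <- read_string_edges(p2, min_confidence = 0.4)
  expect_equal(nrow(net2$edges), 0)

  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB\t1500"), p3)
  expect_error(read_string_edges(p3), "\\[0,1000\\]")
})

test_that("STRING reader output is invariant to row order and endpoint swap", {
  set.seed(11)
  n <- 40
  a <- sprintf("p%02d", sample(20, n, replace = TRUE))
  b <- sprintf("q%02d", sample(20, n, replace = TRUE))
  s <- sample(0:1000, n)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               sprintf("%s\t%s\t%d", a, b, s)), p1)
  perm <- sample(n)
  writeLines(c("protein1\tprotein2\tcombined_score",
               sprintf("%s\t%s\t%d", b[perm], a[perm], s[perm])), p2)
  base <- read_string_edges(p1, 0)
  shuffled <- read_string_edges(p2, 0)
  expect_equal(shuffled$edges, base$edges)
  expect_equal(shuffled$nodes, base$nodes)
})

test_that("orthology, GMT, target-map and Ct tables round-trip", {
  orth <- mk_orth(c("m1", "m2", "m2"), c("h1", "h2", "h3"),
                  c("one2one", "one2many", "one2many"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_orthology(orth, p)
  expect_equal(read_orthology(p)$pairs, orth$pairs)

  gsc <- gene_set_collection(list(T1 = c("a", "b"), T2 = c("c")),
                             c(T1 = "term one", T2 = "term two"))
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc, p2)
  back <- read_gmt(p2)
  expect_equal(back$sets, gsc$sets)
  expect_equal(back$term_names, gsc$term_names)

  tm <- list(mirA = c("g1", "g2"), mirB = "g3")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_target_map(tm, p3)
  expect_equal(read_target_map(p3), tm)

  ct <- synth_ct(c(TG = 2), replicates = 2, seed = 5)
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_ct_csv(ct, p4)
  back_ct <- read_ct_csv(p4)
  expect_equal(back_ct$rows$ct, ct$rows$ct, tolerance = 1e-12)
  expect_equal(back_ct$rows$gene_id, ct$rows$gene_id)
})

test_that("BED intervals are converted to 1-based inclusive coordinates", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tlocusA", "chr2\t500\t500\tsnpB"), p)
  got <- read_bed_loci(p)
  expect_equal(got$start[1], 100)
  expect_equal(got$end[1], 200)
  # zero-length BED record becomes a 1-bp point interval
  expect_equal(got$start[2], 501)
  expect_equal(got$end[2], 501)
})

test_that("type constructors enforce their invariants", {
  expect_error(gene_network(data.frame(a = "x", b = "x", confidence = 0.5)),
               "self-loop")
  expect_error(gene_network(data.frame(a = "x", b = "y", confidence = 1.2)),
               "confidence")
  expect_error(orthology_map(data.frame(mouse_gene_id = c("m", "m"),
                                        human_gene_id = c("h1", "h2"),
                                        relation = "one2one")),
               "one2one")
  expect_error(ct_table(data.frame(sample_id = "s", group = "case",
                                   tissue = "colon", gene_id = "g",
                                   ct = -1)), "Ct")
  expect_error(gene_loci(data.frame(gene_id = "g", chrom = "c", start = 10,
                                    end = 5, strand = "+", biotype = "pcg",
                                    expressed = TRUE)), "start")
  expect_warning(normalize_biotype("pseudogene"), "other")
  expect_equal(suppressWarnings(normalize_biotype(c("protein_coding", "TEC"))),
               c("pcg", "other"))
})
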
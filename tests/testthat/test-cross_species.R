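test_that("concordance classes follow direction pairs and exclude inconsistent genes", {
  m <- mk_sde(c("m1", "m2", "m3", "m4"), c("up", "up", "down", "up"),
              species = "mouse")
  # h4 is significant-but-conflicting in the human combination: excluded
  h <- mk_sde(c("h1", "h2", "h3"), c("up", "down", "down"),
              inconsistent = "h4")
  orth <- mk_orth(c("m1", "m2", "m3", "m4", "m_x"),
                  c("h1", "h2", "h3", "h4", "h_x"))
  expect_error(mk_orth("m1", "h1", "bogus"), "relation")
  ct <- overlap_species(m, h, orth)
  cls <- setNames(ct$rows$class, ct$rows$mouse_gene_id)
  expect_equal(cls[["m1"]], "concordant_up")
  expect_equal(cls[["m2"]], "contra")
  expect_equal(cls[["m3"]], "concordant_down")
  # the inconsistent human gene never yields an overlap row
  expect_false("m4" %in% ct$rows$mouse_gene_id)
  # non-SDE orthologs produce nothing
  expect_false("m_x" %in% ct$rows$mouse_gene_id)
  # ortholog-availability counts (mouse side counts m1..m4, all mapped)
  expect_equal(ct$n_mouse_sde_with_ortholog, 4L)
  expect_equal(ct$n_human_sde_with_ortholog, 3L)
})

test_that("one2many mouse genes are counted once, concordant if any pair is", {
  m <- mk_sde("m1", "up", species = "mouse")
  h <- mk_sde(c("h2", "h3"), c("up", "down"))
  orth <- mk_orth(c("m1", "m1", "m1"), c("h1", "h2", "h3"), "one2many")
  ct <- overlap_species(m, h, orth)
  # h1 not human-SDE: two rows only (via h2 and h3)
  expect_equal(nrow(ct$rows), 2)
  expect_equal(nrow(ct$genes), 1)
  expect_equal(ct$genes$class, "concordant_up")  # any concordant pair wins
  t <- tally_concordance(ct)
  expect_equal(t$n_total_common, 1)
  expect_equal(t$n_up_up, 1)

  # all matched pairs contra -> gene-level contra
  h2 <- mk_sde(c("h2", "h3"), c("down", "down"))
  ct2 <- overlap_species(m, h2, orth)
  expect_equal(ct2$genes$class, "contra")
})

test_that("overlap equals a brute-force pair enumeration on random inputs", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 120
    mg <- sprintf("m%03d", 1:n)
    hg <- sprintf("h%03d", 1:n)
    m_sel <- sample(n, 60)
    h_sel <- sample(n, 60)
    m <- mk_sde(mg[m_sel], sample(c("up", "down"), 60, TRUE),
                species = "mouse")
    h <- mk_sde(hg[h_sel], sample(c("up", "down"), 60, TRUE))
    # random orthology incl. some one2many fan-outs
    pairs <- data.frame(mouse_gene_id = mg, human_gene_id = hg,
                        relation = "one2one", stringsAsFactors = FALSE)
    fan <- sample(n, 10)
    pairs$relation[fan] <- "one2many"
    extra <- data.frame(mouse_gene_id = mg[fan],
                        human_gene_id = sprintf("h%03d_b", fan),
                        relation = "one2many", stringsAsFactors = FALSE)
    orth <- orthology_map(rbind(pairs, extra))
    ct <- overlap_species(m, h, orth)
    # brute force double loop
    brute <- list()
    for (i in seq_len(nrow(orth$pairs))) {
      mi <- orth$pairs$mouse_gene_id[i]
      hi <- orth$pairs$human_gene_id[i]
      if (mi %in% m$entries$gene_id && hi %in% h$entries$gene_id) {
        brute[[length(brute) + 1L]] <- paste(mi, hi)
      }
    }
    expect_setequal(paste(ct$rows$mouse_gene_id, ct$rows$human_gene_id),
                    unlist(brute))
    t <- tally_concordance(ct)
    expect_equal(t$n_total_common, t$n_up_up + t$n_down_down + t$n_contra)
  }
})

test_that("species relabeling with flipped directions preserves class counts", {
  set.seed(32)
  n <- 80
  dirs_m <- sample(c("up", "down"), n, TRUE)
  dirs_h <- sample(c("up", "down"), n, TRUE)
  mg <- sprintf("m%02d", 1:n)
  hg <- sprintf("h%02d", 1:n)
  orth <- mk_orth(mg, hg)
  flip <- function(d) ifelse(d == "up", "down", "up")
  t1 <- tally_concordance(overlap_species(
    mk_sde(mg, dirs_m, species = "mouse"), mk_sde(hg, dirs_h), orth))
  t2 <- tally_concordance(overlap_species(
    mk_sde(mg, flip(dirs_m), species = "mouse"),
    mk_sde(hg, flip(dirs_h)), orth))
  expect_equal(t2$n_contra, t1$n_contra)
  expect_equal(t2$n_same_direction, t1$n_same_direction)
  expect_equal(t2$n_up_up, t1$n_down_down)
})

test_that("tally arithmetic reproduces totals from class counts", {
  t <- tally_concordance(1082, 360, 495)
  expect_equal(t$n_total_common, 1937)
  expect_equal(t$n_same_direction, 1442)
  t2 <- tally_concordance(154, 3, 2)
  expect_equal(t2$n_total_common, 159)
  expect_equal(t2$n_same_direction, 157)
  empty <- overlap_species(mk_sde(character(), character(), species = "mouse"),
                           mk_sde(character(), character()),
                           mk_orth("m1", "h1"))
  t0 <- tally_concordance(empty)
  expect_equal(t0$n_total_common, 0)
  expect_equal(t0$n_same_direction, 0)
})

test_that("core set keeps genes concordant in both tissues, agreement annotated", {
  orth <- mk_orth(c("m1", "m2", "m3", "m4"), c("h1", "h2", "h3", "h4"))
  mk_ct <- function(m_dirs, h_dirs, tissue) {
    overlap_species(
      mk_sde(names(m_dirs), m_dirs, species = "mouse", tissue = tissue),
      mk_sde(names(h_dirs), h_dirs, tissue = tissue), orth)
  }
  colon <- mk_ct(c(m1 = "up", m2 = "down", m3 = "up", m4 = "up"),
                 c(h1 = "up", h2 = "down", h3 = "down", h4 = "up"),
                 "colon")
  blood <- mk_ct(c(m1 = "up", m2 = "up", m4 = "down"),
                 c(h1 = "up", h2 = "up", h4 = "up"), "blood")
  cs <- core_set(colon, blood)
  # m1: up/up in both tissues -> member with agreement
  # m2: down in colon, up in blood (concordant in both) -> member, no agreement
  # m3: concordant in colon only -> excluded
  # m4: contra in blood -> excluded
  expect_setequal(cs$mouse_gene_id, c("m1", "m2"))
  expect_true(cs$cross_tissue_agreement[cs$mouse_gene_id == "m1"])
  expect_false(cs$cross_tissue_agreement[cs$mouse_gene_id == "m2"])
})

test_that("relaxed miRNA threshold is a superset of the stringent one", {
  m_tab <- mk_de(c("mmu_mir1", "mmu_mir2", "mmu_mir3"), c(1, -1, 1),
                 c(0.03, 0.07, 0.2), biotype = "mirna", species = "mouse",
                 dataset_id = "m_small", assay = "small_rna")
  h1 <- mk_de(c("hsa_mir1", "hsa_mir2", "hsa_mir3"), c(1, -1, 1),
              c(0.04, 0.07, 0.5), biotype = "mirna",
              dataset_id = "h_s1", assay = "small_rna")
  h2 <- mk_de(c("hsa_mir1", "hsa_mir2", "hsa_mir3"), c(1, -0.5, 1),
              c(0.5, 0.2, 0.6), biotype = "mirna",
              dataset_id = "h_s2", assay = "small_rna")
  orth <- mk_orth(paste0("mmu_mir", 1:3), paste0("hsa_mir", 1:3))
  strict <- relaxed_mirna_overlap(m_tab, list(h1, h2), orth,
                                  padj_max = 0.05, strict = FALSE)
  relaxed <- relaxed_mirna_overlap(m_tab, list(h1, h2), orth,
                                   padj_max = 0.1)
  expect_true(all(strict$rows$mouse_gene_id %in% relaxed$rows$mouse_gene_id))
  # borderline padj = 0.07 pair enters only under the relaxed cutoff
  expect_false("mmu_mir2" %in% strict$rows$mouse_gene_id)
  expect_true("mmu_mir2" %in% relaxed$rows$mouse_gene_id)
  expect_true("mmu_mir1" %in% strict$rows$mouse_gene_id)
})

test_that("planted cross-species classes are recovered exactly at zero noise", {
  gen <- synth_de(synth_de_config(sigma = 0, tissues = c("colon", "blood")),
                  seed = 12)
  orth <- synth_orthology(gen$truth, seed = 13)
  truth <- gen$truth$genes
  cts <- lapply(c("colon", "blood"), function(tis) {
    m <- Filter(function(t) t$species == "mouse" && t$tissue == tis,
                gen$tables)[[1]]
    h <- Filter(function(t) t$species == "human" && t$tissue == tis,
                gen$tables)
    overlap_species(call_sde(m, lfc_min_total = 0, fc_min_mirna = 1),
                    combine_datasets(h), orth)
  })
  for (ct in cts) {
    t <- tally_concordance(ct)
    expect_equal(t$n_up_up, 50)
    expect_equal(t$n_down_down, 30)
    expect_equal(t$n_contra, 20)
    # zero false positives: every common gene is a planted signal gene
    planted <- truth$mouse_id[truth$class %in%
                                c("concordant_up", "concordant_down", "contra")]
    expect_setequal(ct$genes$mouse_gene_id, planted)
  }
  cs <- core_set(cts[[1]], cts[[2]])
  expect_setequal(cs$mouse_gene_id,
                  truth$mouse_id[truth$class %in% c("concordant_up",
                                                    "concordant_down")])
  expect_true(all(cs$cross_tissue_agreement))
})
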
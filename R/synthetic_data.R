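#' @title Synthetic input generation with planted ground truth
#' @description Generators for every pipeline input — DE tables, orthology,
#'   gene loci, interaction network, gene sets, miRNA target maps and qPCR
#'   Ct tables — with known planted truth, so every downstream stage can be
#'   tested for exact recovery. Adjusted p-values are generated directly
#'   (significant genes draw padj in [0, 0.05], null genes in (0.05, 1])
#'   rather than from simulated counts: the pipeline consumes DE results
#'   tables, so emulating the output distribution suffices and keeps the
#'   generators analytic. All generators are deterministic given their seed.
#' @name synthetic-data
#' @keywords internal
NULL

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

GENE_CLASSES <- c("concordant_up", "concordant_down", "contra",
                  "inconsistent", "species_specific", "null")

#' Configuration for the DE-table generator
#'
#' Class sizes define the planted cross-species structure: genes up (or
#' down) in both species, contra-regulated between species, inconsistent
#' across the human datasets, significant in one species only, and null.
#'
#' @param n_concordant_up,n_concordant_down,n_contra,n_inconsistent,n_species_specific,n_null
#'   class sizes (non-negative integers).
#' @param mu planted effect size in log2FC units (> 0); down-classes use
#'   `-mu`.
#' @param sigma log2FC noise sd (>= 0; 0 gives exact effects).
#' @param fire_prob per-dataset probability that a signal gene is
#'   significant; class minimums (two human datasets for concordant /
#'   contra / inconsistent, one mouse dataset) are always enforced.
#' @param n_human_datasets,n_mouse_datasets datasets per tissue.
#' @param tissues tissues to generate; classes realize identically in every
#'   tissue so concordant genes are also cross-tissue core genes.
#' @param biotype_props named proportions over pcg/lncrna/mirna/other.
#' @param assay assay label for the generated tables.
#' @param dropout per-dataset fraction of genes silently absent from that
#'   dataset's universe (never applied to signal genes, default 0).
#' @return a `synth_de_config` list.
#' @export
synth_de_config <- function(n_concordant_up = 50, n_concordant_down = 30,
                            n_contra = 20, n_inconsistent = 15,
                            n_species_specific = 25, n_null = 500,
                            mu = 3, sigma = 0.5, fire_prob = 1,
                            n_human_datasets = 4, n_mouse_datasets = 1,
                            tissues = c("colon", "blood"),
                            biotype_props = c(pcg = 0.7, lncrna = 0.15,
                                              mirna = 0, other = 0.15),
                            assay = "total_rna", dropout = 0) {
  cfg <- as.list(environment())
  sizes <- unlist(cfg[paste0("n_", GENE_CLASSES)])
  stopifnot(all(sizes >= 0), mu > 0, sigma >= 0, fire_prob > 0,
            fire_prob <= 1, n_human_datasets >= 2, n_mouse_datasets >= 1,
            dropout >= 0, dropout < 1)
  stopifnot(abs(sum(biotype_props) - 1) < 1e-8)
  class(cfg) <- "synth_de_config"
  cfg
}

fire_matrix <- function(n_genes, n_datasets, prob, min_fire) {
  m <- matrix(stats::runif(n_genes * n_datasets) < prob, n_genes, n_datasets)
  short <- which(rowSums(m) < min_fire)
  for (i in short) {
    m[i, sample.int(n_datasets, min_fire)] <- TRUE
  }
  m
}

#' Generate DE tables for both species with planted truth
#'
#' For each dataset, signal genes that fire get `log2fc ~ N(signed mu,
#' sigma)` and `padj ~ U[0, 0.05]`; all other genes get `log2fc ~ N(0,
#' sigma)` and `padj ~ U(0.05, 1]`. Concordant genes share the sign across
#' species; contra genes have opposite signs between species but a
#' consistent sign within each species; inconsistent genes fire in at least
#' two human datasets with both signs present (and stay null in the mouse);
#' species-specific genes fire in one species only (alternating mouse /
#' human).
#'
#' @param config a [synth_de_config()].
#' @param seed integer seed; output is fully deterministic given it.
#' @return list with `tables` (list of [de_table()]) and `truth`
#'   (`planted_truth`: data.frame `genes` with per-gene class, ids and
#'   species signs, plus the config).
#' @export
synth_de <- function(config = synth_de_config(), seed = 1) {
  stopifnot(inherits(config, "synth_de_config"))
  with_seed(seed, {
    sizes <- unlist(config[paste0("n_", GENE_CLASSES)])
    n <- sum(sizes)
    cls <- rep(GENE_CLASSES, times = sizes)
    base_id <- sprintf("g%05d", seq_len(n))
    mouse_id <- paste0("mmu_", base_id)
    human_id <- paste0("hsa_", base_id)
    biotype <- sample(names(config$biotype_props), n, replace = TRUE,
                      prob = config$biotype_props)
    mu <- config$mu
    # species-level signed effects (0 = no planted effect in that species)
    m_sign <- ifelse(cls == "concordant_up", 1,
              ifelse(cls == "concordant_down", -1,
              ifelse(cls == "contra", rep(c(1, -1), length.out = n), 0)))
    h_sign <- ifelse(cls %in% c("concordant_up", "concordant_down"), m_sign,
                     -m_sign)
    h_sign[!cls %in% c("concordant_up", "concordant_down", "contra")] <- 0
    # species-specific genes alternate between mouse-only and human-only
    ss <- which(cls == "species_specific")
    ss_mouse <- ss[seq_along(ss) %% 2 == 1]
    ss_human <- setdiff(ss, ss_mouse)
    m_sign[ss_mouse] <- 1
    h_sign[ss_human] <- 1

    base_mean <- round(2^stats::runif(n, 2, 12), 2)
    truth <- data.frame(gene = base_id, mouse_id = mouse_id,
                        human_id = human_id, class = cls, biotype = biotype,
                        mouse_sign = m_sign, human_sign = h_sign,
                        stringsAsFactors = FALSE)

    make_records <- function(ids, fired, sign_vec, inconsist_sign) {
      eff <- ifelse(fired, sign_vec * mu, 0)
      eff[!is.na(inconsist_sign)] <- (inconsist_sign * mu)[!is.na(inconsist_sign)]
      lfc <- stats::rnorm(n, mean = eff, sd = config$sigma)
      # keep planted signs exact even at sigma > 0 for fired signal genes
      signal <- fired & eff != 0
      flip <- signal & sign(lfc) != sign(eff)
      lfc[flip] <- -lfc[flip]
      padj <- ifelse(fired, stats::runif(n, 0, 0.05),
                     stats::runif(n, 0.0501, 1))
      data.frame(gene_id = ids, biotype = biotype, base_mean = base_mean,
                 log2fc = lfc, pvalue = pmin(padj * 0.9, 1), padj = padj,
                 stringsAsFactors = FALSE)
    }

    tables <- list()
    for (tis in config$tissues) {
      # mouse: fires where a mouse-side effect is planted
      m_signal <- m_sign != 0
      for (d in seq_len(config$n_mouse_datasets)) {
        fired <- rep(FALSE, n)
        fired[m_signal] <- fire_matrix(sum(m_signal), 1, config$fire_prob, 1)
        rec <- make_records(mouse_id, fired, m_sign, rep(NA_real_, n))
        rec <- apply_dropout(rec, config$dropout, protect = m_signal |
                               cls == "inconsistent")
        tables[[length(tables) + 1L]] <-
          de_table(rec, sprintf("mouse_%s_d%d", tis, d), "mouse", tis,
                   config$assay)
      }
      # human: concordant/contra fire in >= 2 datasets; inconsistent fire in
      # >= 2 with both signs; human-only species-specific fire in >= 2
      h_signal <- h_sign != 0
      inc <- cls == "inconsistent"
      k <- config$n_human_datasets
      fmat <- matrix(FALSE, n, k)
      fmat[h_signal | inc, ] <- fire_matrix(sum(h_signal | inc), k,
                                            config$fire_prob, 2)
      inc_sign <- matrix(NA_real_, n, k)
      for (i in which(inc)) {
        d_f <- which(fmat[i, ])
        s <- rep(c(1, -1), length.out = length(d_f))
        inc_sign[i, d_f] <- s
      }
      for (d in seq_len(k)) {
        rec <- make_records(human_id, fmat[, d], h_sign, inc_sign[, d])
        rec <- apply_dropout(rec, config$dropout, protect = h_signal | inc)
        tables[[length(tables) + 1L]] <-
          de_table(rec, sprintf("human_%s_d%d", tis, d), "human", tis,
                   config$assay)
      }
    }
    list(tables = tables,
         truth = structure(list(genes = truth, config = config, seed = seed),
                           class = "planted_truth"))
  })
}

apply_dropout <- function(rec, dropout, protect) {
  if (dropout <= 0) return(rec)
  drop <- stats::runif(nrow(rec)) < dropout & !protect
  rec[!drop, , drop = FALSE]
}

#' Generate an orthology map for a planted gene universe
#'
#' Index-matched mouse/human pairs. A fraction of pairs is upgraded to
#' one-to-many by adding a second human partner (a minted id outside the
#' expression universe, so planted recovery is unaffected); a fraction is
#' dropped (unmapped).
#'
#' @param truth a `planted_truth` from [synth_de()].
#' @param one2many_frac,unmapped_frac fractions in [0,1] with sum <= 1.
#'   One-to-many and unmapped status is only assigned to null genes so that
#'   planted signal classes stay exactly recoverable.
#' @param seed integer seed.
#' @return an [orthology_map()].
#' @export
synth_orthology <- function(truth, one2many_frac = 0, unmapped_frac = 0,
                            seed = 1) {
  stopifnot(inherits(truth, "planted_truth"),
            one2many_frac >= 0, unmapped_frac >= 0,
            one2many_frac + unmapped_frac <= 1)
  with_seed(seed, {
    g <- truth$genes
    pairs <- data.frame(mouse_gene_id = g$mouse_id, human_gene_id = g$human_id,
                        relation = "one2one", stringsAsFactors = FALSE)
    nulls <- which(g$class == "null")
    n_o2m <- round(one2many_frac * nrow(g))
    n_un <- round(unmapped_frac * nrow(g))
    pick <- sample(nulls, min(length(nulls), n_o2m + n_un))
    o2m <- utils::head(pick, n_o2m)
    un <- utils::tail(pick, length(pick) - length(o2m))
    if (length(o2m)) {
      pairs$relation[o2m] <- "one2many"
      extra <- data.frame(mouse_gene_id = g$mouse_id[o2m],
                          human_gene_id = paste0(g$human_id[o2m], "_par"),
                          relation = "one2many", stringsAsFactors = FALSE)
      pairs <- rbind(pairs, extra)
    }
    if (length(un)) {
      pairs <- pairs[!pairs$mouse_gene_id %in% g$mouse_id[un], , drop = FALSE]
    }
    orthology_map(pairs)
  })
}

#' Generate gene loci on synthetic chromosomes
#'
#' Genes are placed uniformly (overlap allowed) with lncRNAs interleaved
#' among PCGs; the brute-force within-window neighbour list of every lncRNA
#' is computed at generation time and returned as ground truth.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length in bp.
#' @param n_chroms number of chromosomes.
#' @param lncrna_frac fraction of lncRNA genes (rest are PCGs).
#' @param window_bp window used for the truth neighbour lists.
#' @param seed integer seed.
#' @param gene_ids,biotypes optional length-`n_genes` overrides so loci can
#'   be generated for an existing gene universe.
#' @return list with `loci` ([gene_loci()]), `neighbors_truth` (named list:
#'   lncRNA id -> sorted PCG ids) and `window_bp`.
#' @export
synth_loci <- function(n_genes, chrom_length = 5e6, n_chroms = 2,
                       lncrna_frac = 0.2, window_bp = 100000, seed = 1,
                       gene_ids = NULL, biotypes = NULL) {
  if (n_genes == 0) {
    return(list(loci = gene_loci(data.frame(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), biotype = character(),
      expressed = logical())), neighbors_truth = list(),
      window_bp = window_bp))
  }
  with_seed(seed, {
    biotype <- if (!is.null(biotypes)) biotypes else
      ifelse(seq_len(n_genes) %% round(1 / max(lncrna_frac, 1e-9)) == 0,
             "lncrna", "pcg")
    ids <- if (!is.null(gene_ids)) gene_ids else
      sprintf("loc_g%04d", seq_len(n_genes))
    stopifnot(length(biotype) == n_genes, length(ids) == n_genes)
    len <- sample(500:5000, n_genes, replace = TRUE)
    start <- sample.int(chrom_length - max(len), n_genes, replace = TRUE)
    loci <- gene_loci(data.frame(
      gene_id = ids,
      chrom = paste0("chrS", sample.int(n_chroms, n_genes, replace = TRUE)),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      biotype = biotype, expressed = TRUE, stringsAsFactors = FALSE))
    lnc <- loci$gene_id[loci$biotype == "lncrna"]
    truth <- lapply(lnc, function(id) {
      i <- match(id, loci$gene_id)
      hits <- character()
      for (j in seq_len(nrow(loci))) {       # deliberate quadratic oracle
        if (loci$biotype[j] != "pcg" || j == i) next
        if (loci$chrom[j] != loci$chrom[i]) next
        if (loci$start[j] <= loci$end[i] + window_bp &&
            loci$end[j] >= loci$start[i] - window_bp) {
          hits <- c(hits, loci$gene_id[j])
        }
      }
      sort(hits)
    })
    names(truth) <- lnc
    list(loci = loci, neighbors_truth = truth, window_bp = window_bp)
  })
}

#' Generate a star-plus-noise interaction network with planted hubs
#'
#' Each hub is connected to at least `hub_frac` of the core genes at
#' confidence 0.9; noise edges are Erdos-Renyi among all nodes at
#' confidences uniform in [0.41, 0.6].
#'
#' @param core_genes character vector of core gene ids.
#' @param n_noise_nodes number of extra noise-only nodes.
#' @param hub_ids character vector of planted hub ids (subset of
#'   `core_genes` or new ids).
#' @param noise_p Erdos-Renyi edge probability for noise edges, default 0.05.
#' @param hub_frac fraction of core genes each hub connects to, default 0.9.
#' @param seed integer seed.
#' @return list with `network` ([gene_network()]) and `hub_ids`.
#' @export
synth_network <- function(core_genes, n_noise_nodes = 0, hub_ids = character(),
                          noise_p = 0.05, hub_frac = 0.9, seed = 1) {
  stopifnot(hub_frac >= 0.8)  # planted hubs must dominate by construction
  with_seed(seed, {
    noise_nodes <- if (n_noise_nodes > 0) sprintf("noise_%03d",
                                                  seq_len(n_noise_nodes))
                   else character()
    nodes <- unique(c(core_genes, hub_ids, noise_nodes))
    edges <- data.frame(a = character(), b = character(),
                        confidence = numeric())
    for (h in hub_ids) {
      partners <- setdiff(core_genes, h)
      k <- ceiling(hub_frac * length(partners))
      sel <- sample(partners, k)
      edges <- rbind(edges, data.frame(a = h, b = sel, confidence = 0.9))
    }
    others <- setdiff(nodes, hub_ids)
    if (length(others) > 1 && noise_p > 0) {
      cmb <- utils::combn(sort(others), 2)
      pick <- stats::runif(ncol(cmb)) < noise_p
      if (any(pick)) {
        edges <- rbind(edges, data.frame(
          a = cmb[1, pick], b = cmb[2, pick],
          confidence = stats::runif(sum(pick), 0.41, 0.6)))
      }
    }
    list(network = gene_network(edges, nodes = nodes), hub_ids = hub_ids)
  })
}

#' Generate a qPCR Ct table consistent with planted fold changes
#'
#' Target Ct in cases is `control Ct - log2(planted FC)` plus measurement
#' noise; reference genes are constant across groups up to noise. At
#' `noise_sd = 0` the 2^-ddCt estimate recovers every planted fold change
#' exactly.
#'
#' @param planted_fc named numeric vector: target gene id -> fold change
#'   (> 0).
#' @param reference_genes character vector of reference gene ids.
#' @param n_case,n_control samples per group.
#' @param replicates technical replicates per (sample, gene).
#' @param noise_sd Ct measurement noise sd.
#' @param base_ct,ref_ct baseline Ct of targets / references.
#' @param tissue tissue label.
#' @param seed integer seed.
#' @return a [ct_table()].
#' @export
synth_ct <- function(planted_fc, reference_genes = c("GUSB", "B2M", "ACTB",
                                                     "TBP"),
                     n_case = 5, n_control = 5, replicates = 3,
                     noise_sd = 0, base_ct = 25, ref_ct = 20,
                     tissue = "colon", seed = 1) {
  stopifnot(all(planted_fc > 0), !is.null(names(planted_fc)))
  with_seed(seed, {
    samples <- data.frame(
      sample_id = c(sprintf("case_%02d", seq_len(n_case)),
                    sprintf("ctrl_%02d", seq_len(n_control))),
      group = rep(c("case", "control"), c(n_case, n_control)),
      stringsAsFactors = FALSE)
    genes <- data.frame(
      gene_id = c(names(planted_fc), reference_genes),
      is_ref = rep(c(FALSE, TRUE), c(length(planted_fc),
                                     length(reference_genes))),
      stringsAsFactors = FALSE)
    grid <- merge(merge(samples, genes), data.frame(rep = seq_len(replicates)))
    mu <- ifelse(grid$is_ref, ref_ct,
                 base_ct - ifelse(grid$group == "case",
                                  log2(planted_fc[grid$gene_id]), 0))
    grid$ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
    grid$tissue <- tissue
    ct_table(grid[c("sample_id", "group", "tissue", "gene_id", "ct")])
  })
}

#' Generate a miRNA-to-target map
#'
#' @param mirna_ids character vector of miRNA ids.
#' @param universe character vector of candidate target gene ids.
#' @param n_targets targets per miRNA (sampled without replacement).
#' @param uncovered_frac fraction of miRNAs left out of the map entirely.
#' @param seed integer seed.
#' @return named list: miRNA id -> character vector of target ids.
#' @export
synth_target_map <- function(mirna_ids, universe, n_targets = 20,
                             uncovered_frac = 0, seed = 1) {
  with_seed(seed, {
    n_un <- round(uncovered_frac * length(mirna_ids))
    covered <- if (n_un > 0) {
      setdiff(mirna_ids, sample(mirna_ids, n_un))
    } else mirna_ids
    out <- lapply(covered, function(m) {
      sort(sample(universe, min(n_targets, length(universe))))
    })
    names(out) <- covered
    out
  })
}

#' Generate a gene-set collection with one planted enriched term
#'
#' Random terms draw members uniformly from the universe; the planted term
#' consists of the supplied genes (over-represented in any query that
#' contains them).
#'
#' @param universe character vector of gene ids.
#' @param n_sets number of random terms.
#' @param set_size integer range `c(min, max)` of random term sizes.
#' @param planted_genes optional character vector forming the planted term
#'   `SYNTH_PLANTED`.
#' @param seed integer seed.
#' @return a [gene_set_collection()].
#' @export
synth_genesets <- function(universe, n_sets = 10, set_size = c(10, 50),
                           planted_genes = NULL, seed = 1) {
  with_seed(seed, {
    sizes <- sample(set_size[1]:set_size[2], n_sets, replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) {
      sort(sample(universe, min(sizes[i], length(universe))))
    })
    names(sets) <- sprintf("SYNTH%03d", seq_len(n_sets))
    term_names <- stats::setNames(sprintf("synthetic term %d",
                                          seq_len(n_sets)), names(sets))
    if (!is.null(planted_genes)) {
      sets$SYNTH_PLANTED <- sort(planted_genes)
      term_names["SYNTH_PLANTED"] <- "planted enriched term"
    }
    gene_set_collection(sets, term_names)
  })
}

#' Generate risk-locus intervals near a chosen subset of genes
#'
#' Places one risk interval within `window_bp` of each selected gene (so
#' those genes are flagged by construction) on the gene's chromosome.
#'
#' @param loci a [gene_loci()] data.frame.
#' @param flagged_ids gene ids that must end up within range of a locus.
#' @param window_bp proximity window, default 100000.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `start`, `end`, `name` (1-based
#'   inclusive).
#' @export
synth_risk_loci <- function(loci, flagged_ids, window_bp = 100000, seed = 1) {
  with_seed(seed, {
    idx <- match(flagged_ids, loci$gene_id)
    stopifnot(!anyNA(idx))
    off <- sample.int(window_bp, length(idx), replace = TRUE)
    start <- pmax(1L, loci$start[idx] - off)
    data.frame(chrom = loci$chrom[idx], start = start, end = start + 99L,
               name = sprintf("risk_%03d", seq_along(idx)),
               stringsAsFactors = FALSE)
  })
}
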
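#' @title End-to-end pipeline orchestration
#' @description Runs the whole analysis from one structured configuration:
#'   (optionally) generate a synthetic input bundle, call per-dataset SDE
#'   sets, combine the human datasets, overlap species through orthology,
#'   extract the cross-tissue core set, annotate genomic context, run
#'   enrichment, rank genes by combined network centrality and quantify the
#'   qPCR panel. Every intermediate is written to disk and the summary
#'   report satisfies the tally identities (total common = up/up + down/down
#'   + contra; same direction = up/up + down/down). Output is deterministic
#'   given config + seed and contains no timestamps, so reruns are
#'   byte-identical.
#' @name pipeline
#' @keywords internal
NULL

DEFAULT_THRESHOLDS <- list(
  padj_max = 0.05, lfc_min_total = 1.0, fc_min_mirna = 1.5,
  min_support = 2, relaxed_padj = 0.1, window_bp = 100000,
  string_min_confidence = 0.4, centrality_weights = c(1, 1, 1) / 3)

#' Build and validate a run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for all randomness in the run.
#' @param synth `TRUE` to generate a synthetic input bundle under
#'   `out_dir/inputs`, or a named list of [synth_de_config()] overrides;
#'   `FALSE` to use `inputs`.
#' @param inputs named list of input paths when `synth = FALSE`:
#'   `de_tables` (list of lists with `path`, `dataset_id`, `species`,
#'   `tissue`, `assay`), `orthology`, and optionally `gtf`, `risk_bed`,
#'   `target_map`, `gmt`, `string_edges`, `ct_csv`.
#' @param thresholds named list overriding any of: `padj_max`,
#'   `lfc_min_total`, `fc_min_mirna`, `min_support`, `relaxed_padj`,
#'   `window_bp`, `string_min_confidence`, `centrality_weights`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, synth = TRUE, inputs = NULL,
                       thresholds = list()) {
  unknown <- setdiff(names(thresholds), names(DEFAULT_THRESHOLDS))
  if (length(unknown)) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  thr <- utils::modifyList(DEFAULT_THRESHOLDS, thresholds)
  stopifnot(thr$padj_max > 0, thr$padj_max <= 1, thr$lfc_min_total >= 0,
            thr$fc_min_mirna >= 1, thr$min_support >= 1,
            thr$relaxed_padj > 0, thr$window_bp > 0,
            thr$string_min_confidence >= 0, thr$string_min_confidence <= 1,
            length(thr$centrality_weights) == 3)
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 inputs = inputs, thresholds = thr),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys: `out_dir`, `seed`, `synth`, `inputs`, `thresholds`
#' (see [run_config()]); unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "synth", "inputs", "thresholds")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop(path, ": unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

#' Write a complete synthetic input bundle
#'
#' Generates every pipeline input with one consistent planted truth and
#' writes it to `dir`: DE TSVs (per dataset), a GTF of the mouse gene loci,
#' the orthology TSV, a STRING-dialect edge TSV with planted hubs among the
#' concordant genes, a GMT collection with one planted term, a miRNA target
#' map, risk-locus BED-style TSV, a Ct CSV with planted fold changes, and
#' `truth.json`.
#'
#' @param dir output directory.
#' @param config a [synth_de_config()].
#' @param seed integer seed.
#' @return invisibly, a list with the `truth` and a manifest of paths.
#' @export
synth_bundle <- function(dir, config = synth_de_config(), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- synth_de(config, seed = seed)
  g <- gen$truth$genes
  manifest <- list(de_tables = list())
  for (t in gen$tables) {
    p <- file.path(dir, paste0("de_", t$dataset_id, ".tsv"))
    write_de_table(t, p)
    manifest$de_tables[[length(manifest$de_tables) + 1L]] <-
      list(path = p, dataset_id = t$dataset_id, species = t$species,
           tissue = t$tissue, assay = t$assay)
  }
  orth <- synth_orthology(gen$truth, seed = seed + 1)
  manifest$orthology <- file.path(dir, "orthology.tsv")
  write_orthology(orth, manifest$orthology)

  sl <- synth_loci(nrow(g), seed = seed + 2, gene_ids = g$mouse_id,
                   biotypes = g$biotype)
  manifest$gtf <- file.path(dir, "loci.gtf")
  write_gtf_loci(sl$loci, manifest$gtf)

  conc <- g$mouse_id[g$class %in% c("concordant_up", "concordant_down")]
  hubs <- utils::head(conc, 2)
  net <- synth_network(conc, n_noise_nodes = 20, hub_ids = hubs,
                       seed = seed + 3)
  manifest$string_edges <- file.path(dir, "string_edges.tsv")
  write_string_edges(net$network, manifest$string_edges)

  gmt <- synth_genesets(g$human_id, planted_genes =
                          utils::head(g$human_id[g$class == "concordant_up"],
                                      20), seed = seed + 4)
  manifest$gmt <- file.path(dir, "genesets.gmt")
  write_gmt(gmt, manifest$gmt)

  tmap <- synth_target_map(paste0("mir_", utils::head(g$gene, 10)),
                           g$human_id, seed = seed + 5)
  manifest$target_map <- file.path(dir, "target_map.tsv")
  write_target_map(tmap, manifest$target_map)

  risk_genes <- utils::head(g$mouse_id[g$class == "concordant_up"], 5)
  risk <- synth_risk_loci(sl$loci, risk_genes, seed = seed + 6)
  manifest$risk_tsv <- file.path(dir, "risk_loci.tsv")
  utils::write.table(risk, manifest$risk_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  fc_genes <- utils::head(conc, 4)
  planted_fc <- stats::setNames(c(4, 2, 0.5, 8)[seq_along(fc_genes)],
                                fc_genes)
  ct <- synth_ct(planted_fc, seed = seed + 7)
  manifest$ct_csv <- file.path(dir, "ct.csv")
  write_ct_csv(ct, manifest$ct_csv)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(genes = g, planted_fc = as.list(planted_fc), hubs = hubs,
         neighbors = sl$neighbors_truth, seed = seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  manifest$truth <- truth_path
  invisible(list(truth = gen$truth, manifest = manifest,
                 planted_fc = planted_fc, hubs = hubs,
                 neighbors_truth = sl$neighbors_truth, loci = sl$loci))
}

read_de_inputs <- function(de_specs) {
  lapply(de_specs, function(s) {
    read_de_table(s$path, s$dataset_id, s$species, s$tissue, s$assay)
  })
}

#' Run the full pipeline
#'
#' @param config a `run_config` (see [run_config()]) or path to a YAML
#'   config file.
#' @return invisibly, the run report: a named list with per-tissue SDE
#'   tallies, combined-set sizes, concordance tallies, the core set, the
#'   top-ranked genes, enrichment results and qPCR fold changes. Also
#'   written to `out_dir` as TSVs plus `report.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  thr <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name),
                 file.path(config$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- config$inputs
  bundle <- NULL
  if (!isFALSE(config$synth)) {
    scfg <- if (is.list(config$synth)) do.call(synth_de_config, config$synth)
            else synth_de_config()
    bundle <- stage("synth", synth_bundle(file.path(config$out_dir, "inputs"),
                                          scfg, seed = config$seed))
    m <- bundle$manifest
    inputs <- list(de_tables = m$de_tables, orthology = m$orthology,
                   gtf = m$gtf, risk_tsv = m$risk_tsv,
                   target_map = m$target_map, gmt = m$gmt,
                   string_edges = m$string_edges, ct_csv = m$ct_csv)
  }

  tables <- stage("read_de", read_de_inputs(inputs$de_tables))
  orth <- stage("read_orthology", read_orthology(inputs$orthology))
  tissues <- unique(vapply(tables, `[[`, "", "tissue"))

  report <- list(seed = config$seed, thresholds = thr, tissues = tissues)
  concordance <- list()
  for (tis in tissues) {
    mouse_t <- Filter(function(t) t$species == "mouse" && t$tissue == tis,
                      tables)
    human_t <- Filter(function(t) t$species == "human" && t$tissue == tis,
                      tables)
    # thresholded mouse SDE call (summary-table shape)
    m_sde_thr <- stage("sde", call_sde(mouse_t[[1]], thr$padj_max,
                                       thr$lfc_min_total, thr$fc_min_mirna))
    tally <- tally_by_biotype(m_sde_thr, mouse_t[[1]])
    utils::write.table(tally, file.path(config$out_dir,
                                        sprintf("sde_tally_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # significance-only call for the cross-species overlap
    m_sde <- call_sde(mouse_t[[1]], thr$padj_max, lfc_min_total = 0,
                      fc_min_mirna = 1)
    h_comb <- stage("combine", combine_datasets(human_t, thr$padj_max,
                                                thr$min_support))
    write_sde_set(h_comb, file.path(config$out_dir,
                                    sprintf("combined_human_%s.tsv", tis)))
    ct <- stage("overlap", overlap_species(m_sde, h_comb, orth))
    concordance[[tis]] <- ct
    utils::write.table(ct$rows,
                       file.path(config$out_dir,
                                 sprintf("concordance_pairs_%s.tsv", tis)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$sde_tally[[tis]] <- tally
    report$combined[[tis]] <- list(n_entries = nrow(h_comb$entries),
                                   n_inconsistent = length(h_comb$inconsistent))
    report$concordance[[tis]] <- tally_concordance(ct)
  }

  if (all(c("colon", "blood") %in% tissues)) {
    cs <- stage("core_set", core_set(concordance$colon, concordance$blood))
    utils::write.table(cs, file.path(config$out_dir, "core_set.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$core_set <- cs
  }

  if (!is.null(inputs$gtf)) {
    first <- concordance[[1]]
    expressed <- unique(unlist(lapply(tables, function(t)
      if (t$species == "mouse") t$records$gene_id else character())))
    loci <- stage("read_gtf", read_gtf_loci(inputs$gtf, expressed))
    lnc <- intersect(first$genes$mouse_gene_id,
                     loci$gene_id[loci$biotype == "lncrna"])
    if (length(lnc)) {
      nb <- stage("neighbors", lncrna_neighbors(lnc, loci, thr$window_bp))
      nb_df <- data.frame(
        lncrna_id = rep(names(nb$neighbors), lengths(nb$neighbors)),
        neighbor_id = unlist(nb$neighbors, use.names = FALSE))
      utils::write.table(nb_df, file.path(config$out_dir, "lnc_neighbors.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$n_lnc_neighbors <- nrow(nb_df)
    }
    if (!is.null(inputs$risk_tsv)) {
      risk <- utils::read.table(inputs$risk_tsv, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      cand <- intersect(first$genes$mouse_gene_id, loci$gene_id)
      flagged <- stage("risk", risk_locus_proximity(cand, loci, risk,
                                                    thr$window_bp))
      writeLines(flagged, file.path(config$out_dir, "risk_flagged.tsv"))
      report$n_risk_flagged <- length(flagged)
    }
  }

  if (!is.null(inputs$gmt)) {
    collection <- stage("read_gmt", read_gmt(inputs$gmt))
    universe <- unique(unlist(lapply(tables, function(t)
      if (t$species == "human") t$records$gene_id else character())))
    first <- concordance[[1]]
    query <- unique(first$rows$human_gene_id[first$rows$class != "contra"])
    enr <- stage("enrich", enrich(query, universe, collection))
    utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$enrichment <- enr
  }

  if (!is.null(inputs$string_edges)) {
    net <- stage("read_edges", read_string_edges(inputs$string_edges,
                                                 thr$string_min_confidence))
    ranked <- stage("rank", combined_rank(centralities(net),
                                          weights = thr$centrality_weights))
    utils::write.table(ranked, file.path(config$out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$ranking <- ranked
  }

  if (!is.null(inputs$ct_csv)) {
    ctab <- stage("read_ct", read_ct_csv(inputs$ct_csv))
    targets <- setdiff(unique(ctab$rows$gene_id),
                       c("GUSB", "B2M", "ACTB", "TBP"))
    fc <- stage("qpcr", ddct_fold_change(ctab, targets,
                                         c("GUSB", "B2M", "ACTB", "TBP")))
    utils::write.table(fc, file.path(config$out_dir, "qpcr_fc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$qpcr <- fc
  }

  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  invisible(report)
}

format_report <- function(report) {
  out <- c("ucsig run report",
           sprintf("seed: %d", report$seed),
           sprintf("config_hash: %s",
                   substr(digest_simple(report$thresholds), 1, 12)),
           "")
  for (tis in report$tissues) {
    t <- report$sde_tally[[tis]]
    out <- c(out, sprintf("[%s] mouse SDE by biotype (up/down):", tis),
             sprintf("  %s: %d (%d up, %d down)", t$biotype, t$n_total,
                     t$n_up, t$n_down),
             sprintf("  grand total: %d", attr(t, "grand_total")))
    cb <- report$combined[[tis]]
    out <- c(out, sprintf("[%s] human combined: %d entries, %d inconsistent",
                          tis, cb$n_entries, cb$n_inconsistent))
    cc <- report$concordance[[tis]]
    out <- c(out, sprintf(
      "[%s] common genes: %d (up/up %d, down/down %d, contra %d; same direction %d)",
      tis, cc$n_total_common, cc$n_up_up, cc$n_down_down, cc$n_contra,
      cc$n_same_direction), "")
  }
  if (!is.null(report$core_set)) {
    out <- c(out, sprintf("core set: %d genes (%d cross-tissue agreement)",
                          nrow(report$core_set),
                          sum(report$core_set$cross_tissue_agreement)))
  }
  if (!is.null(report$ranking)) {
    top <- utils::head(report$ranking, 5)
    out <- c(out, "top ranked genes:",
             sprintf("  %d. %s (combined %.4f)", top$rank, top$node,
                     top$combined))
  }
  if (!is.null(report$qpcr)) {
    out <- c(out, "qPCR fold changes:",
             sprintf("  %s [%s]: %.3f", report$qpcr$gene_id,
                     report$qpcr$tissue, report$qpcr$fold_change))
  }
  out
}

digest_simple <- function(x) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_len(nchar(s))) %% .Machine$integer.max)
}
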
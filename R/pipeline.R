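#' Pipeline run configuration
#'
#' Exactly one of \code{input} (paths to vcf / panel / loci, optionally
#' prs_loci) or \code{simulation} (a [sim_config()]) must be given. All
#' randomness (permutations, Markov chains, simulation) flows from the named
#' seeds recorded in the manifest.
#'
#' @param input named list with \code{vcf}, \code{panel}, \code{loci} and
#'   optionally \code{prs_loci} paths, or NULL.
#' @param simulation a [sim_config()], or NULL.
#' @param levels analysis levels to run (subset of superpop/subpop).
#' @param n_perm permutations for the PhiPT tests.
#' @param fdr FDR threshold for the enrichment stage.
#' @param prs_mode risk-score mode.
#' @param g_test_flavor exact-test flavor used in the differentiation stage.
#' @param seed master seed; stage seeds derive from it.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       levels = "superpop", n_perm = 999, fdr = 0.05,
                       prs_mode = "unweighted", g_test_flavor = "genic",
                       seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of input or simulation must be given")
  if (!is.null(input))
    stopifnot(all(c("vcf", "panel", "loci") %in% names(input)))
  stopifnot(all(levels %in% c("superpop", "subpop")))
  structure(list(input = input, simulation = simulation, levels = levels,
                 n_perm = n_perm, fdr = fdr, prs_mode = prs_mode,
                 g_test_flavor = g_test_flavor, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(population = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Executes ingest/simulate, population statistics, differentiation,
#' enrichment and risk-score stages in dependency order, writing every output
#' as TSV under \code{out_dir} plus a \code{manifest.json} listing each file
#' with its stage, parameters and md5 content hash. A rerun with the same
#' config and seeds reproduces every file byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a data.frame.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, params = "") manifest[[length(manifest) + 1L]] <<-
    data.frame(stage = stage, file = basename(file), params = params,
               md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)

  # --- stage 1: ingest or simulate ---------------------------------------
  if (!is.null(config$simulation)) {
    ds <- simulate_dataset(config$simulation)
    dm <- ds$dosage
    prs_loci <- ds$loci
    f <- write_tsv(data.frame(population = rownames(ds$truth$freq),
                              ds$truth$freq, check.names = FALSE),
                   file.path(out_dir, "sim_truth.tsv"))
    note("simulate", f, paste0("seed=", config$simulation$seed))
  } else {
    loci <- read_locus_table(config$input$loci)
    panel <- read_panel(config$input$panel)
    dm <- build_dosage_matrix(config$input$vcf, loci, panel)
    prs_loci <- if (!is.null(config$input$prs_loci))
      read_locus_table(config$input$prs_loci) else dm$loci
    if (nrow(dm$drops)) {
      f <- write_tsv(dm$drops, file.path(out_dir, "dropped_loci.tsv"))
      note("ingest", f)
    }
  }

  for (level in config$levels) {
    tag <- function(name) file.path(out_dir, paste0(name, "_", level, ".tsv"))

    # --- stage 2: population statistics ----------------------------------
    freqs <- allele_frequencies(dm, level)
    note("popstats", write_tsv(freqs, tag("allele_freq")))
    cen <- monomorph_census(freqs)
    note("popstats", write_tsv(cen$per_population, tag("monomorph_census")))
    hwe <- hwe_test(dm, level)
    note("popstats", write_tsv(hwe, tag("hwe")))
    note("popstats", write_tsv(hwe_departures(hwe), tag("hwe_departures")))
    div <- diversity(dm, level)
    note("popstats", write_tsv(div$summary, tag("diversity")))

    # --- stage 3: differentiation ----------------------------------------
    dmx <- differentiation_matrix(dm, level, n_perm = config$n_perm,
                                  seed = config$seed + 101L)
    note("differentiation", write_matrix_tsv(dmx$combined,
         tag("phi_nei_matrix")),
         paste0("n_perm=", config$n_perm, ";seed=", config$seed + 101L))
    note("differentiation", write_matrix_tsv(dmx$phi_p, tag("phi_p")))
    pc <- pcoa(dmx$phi)
    coords <- data.frame(population = rownames(pc$points), pc$points,
                         check.names = FALSE)
    note("differentiation", write_tsv(coords, tag("pcoa")))
    note("differentiation",
         write_tsv(data.frame(axis = seq_along(pc$percent),
                              percent_variance = pc$percent),
                   tag("pcoa_variance")))
    pops <- sort(unique(group_labels(dm, level)))
    gt_rows <- list()
    for (a in seq_len(length(pops) - 1)) for (b in (a + 1):length(pops)) {
      gt <- exact_g_test(dm, level, c(pops[a], pops[b]),
                         flavor = config$g_test_flavor,
                         seed = config$seed + 211L)
      gt_rows[[length(gt_rows) + 1L]] <-
        data.frame(pop1 = pops[a], pop2 = pops[b], X2 = gt$combined$X2,
                   df = gt$combined$df, p = gt$combined$p,
                   stringsAsFactors = FALSE)
    }
    note("differentiation", write_tsv(do.call(rbind, gt_rows),
         tag("g_test_combined")),
         paste0("flavor=", config$g_test_flavor))

    # --- stage 4: enrichment ---------------------------------------------
    if (all(table(group_labels(dm, level)) < nrow(dm$panel))) {
      enr <- hypergeom_enrichment(freqs, fdr = config$fdr)
      note("enrichment", write_tsv(enr, tag("enrichment")),
           paste0("fdr=", config$fdr))
      m <- enrichment_matrix(enr)
      ords <- cluster_orders(m)
      note("enrichment", write_matrix_tsv(
        m[ords$row_order, ords$col_order, drop = FALSE],
        tag("enrichment_matrix_clustered")))
    }
  }

  # --- stage 5: risk scores ----------------------------------------------
  prs <- compute_prs(dm, prs_loci, mode = config$prs_mode)
  note("prs", write_tsv(prs$scores, file.path(out_dir, "prs_scores.tsv")),
       paste0("mode=", config$prs_mode, ";n_loci=", prs$n_loci))
  note("prs", write_tsv(prs$summary, file.path(out_dir, "prs_summary.tsv")))
  for (level in config$levels) {
    cmp <- compare_groups(prs, level)
    if (!is.null(cmp$pairs))
      note("prs", write_tsv(cmp$pairs,
           file.path(out_dir, paste0("prs_pairwise_", level, ".tsv"))),
           sprintf("KW_H=%.6g;KW_p=%.6g", cmp$kw$H, cmp$kw$p))
  }

  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(manifest)
}
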
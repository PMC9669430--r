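#' Pipeline configuration
#'
#' Collects the input paths, stage parameters and seed for a full pipeline
#' run. With `simulate = TRUE` (the default) the input files are generated
#' into `outdir/inputs` by [simulate_dataset()] and the path fields are
#' filled in automatically; otherwise every input path must point to an
#' existing file.
#'
#' @param outdir Output directory for stage TSVs.
#' @param seed Global seed; stage seeds are derived from it.
#' @param simulate Generate the inputs with the bundled simulator?
#' @param sim Simulator configuration ([sim_config()]); its seed is forced
#'   to `seed`.
#' @param reference_gtf,assembly_gtf,transcripts_fa,counts_tsv,groups_tsv,lengths_tsv,precursors_fa,gene_sets_gmt
#'   Input paths (ignored when `simulate = TRUE`).
#' @param min_len,orf_min,fickett_cut,cov_min Discovery parameters.
#' @param de_method,pseudocount,fc_cut,q_cut Differential-expression
#'   parameters.
#' @param window Cis-target window in bp (strict `<`).
#' @param min_identity,min_coverage Precursor-scan thresholds.
#' @param top_k Number of top enrichment terms reported.
#' @param stages Character vector of stages to run, in dependency order, a
#'   subset of `c("simulate", "discover", "quantify", "de", "integrate",
#'   "enrich")`.
#' @return A `lnc_pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, simulate = TRUE,
                            sim = sim_config(seed = seed),
                            reference_gtf = NULL, assembly_gtf = NULL,
                            transcripts_fa = NULL, counts_tsv = NULL,
                            groups_tsv = NULL, lengths_tsv = NULL,
                            precursors_fa = NULL, gene_sets_gmt = NULL,
                            min_len = 200, orf_min = 300, fickett_cut = 0.95,
                            cov_min = 0.5, de_method = "t_logfpkm",
                            pseudocount = 1, fc_cut = 2, q_cut = 0.05,
                            window = 100000, min_identity = 0.9,
                            min_coverage = 0.9, top_k = 20,
                            stages = c("simulate", "discover", "quantify",
                                       "de", "integrate", "enrich")) {
  sim$seed <- as.integer(seed)
  cfg <- list(outdir = outdir, seed = as.integer(seed), simulate = simulate,
              sim = sim,
              paths = list(reference_gtf = reference_gtf,
                           assembly_gtf = assembly_gtf,
                           transcripts_fa = transcripts_fa,
                           counts_tsv = counts_tsv, groups_tsv = groups_tsv,
                           lengths_tsv = lengths_tsv,
                           precursors_fa = precursors_fa,
                           gene_sets_gmt = gene_sets_gmt),
              min_len = min_len, orf_min = orf_min, fickett_cut = fickett_cut,
              cov_min = cov_min, de_method = de_method,
              pseudocount = pseudocount, fc_cut = fc_cut, q_cut = q_cut,
              window = window, min_identity = min_identity,
              min_coverage = min_coverage, top_k = top_k, stages = stages)
  structure(cfg, class = "lnc_pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks that the configured input files exist and parse, that chromosome
#' names are consistent between the annotation and the assembly, and that
#' the count matrix and group sidecar agree. Problems are classified as
#' errors (block a run) or warnings.
#'
#' @param config A [pipeline_config()] object.
#' @return A tibble (`level`, `message`); zero `error` rows means the run
#'   can proceed.
#' @export
validate_inputs <- function(config) {
  probs <- list()
  note <- function(level, msg) probs[[length(probs) + 1]] <<- tibble(level = level, message = msg)
  if (isTRUE(config$simulate)) {
    return(tibble(level = character(), message = character()))
  }
  paths <- config$paths
  needed <- c("reference_gtf", "assembly_gtf", "transcripts_fa", "counts_tsv",
              "groups_tsv", "lengths_tsv", "precursors_fa", "gene_sets_gmt")
  for (nm in needed) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      note("error", sprintf("input '%s' missing or not found: %s", nm,
                            paths[[nm]] %||% "<unset>"))
    }
  }
  if (any(vapply(probs, function(p) p$level == "error", logical(1)))) {
    return(bind_rows(probs))
  }
  ref <- tryCatch(read_gtf(paths$reference_gtf), error = function(e) e)
  asm <- tryCatch(read_gtf(paths$assembly_gtf), error = function(e) e)
  if (inherits(ref, "error")) note("error", paste("reference GTF unreadable:", conditionMessage(ref)))
  if (inherits(asm, "error")) note("error", paste("assembly GTF unreadable:", conditionMessage(asm)))
  counts <- tryCatch(readr::read_tsv(paths$counts_tsv, show_col_types = FALSE),
                     error = function(e) e)
  groups <- tryCatch(readr::read_tsv(paths$groups_tsv, show_col_types = FALSE),
                     error = function(e) e)
  if (inherits(counts, "error")) note("error", "counts TSV unreadable")
  if (inherits(groups, "error")) note("error", "groups TSV unreadable")
  if (!inherits(ref, "error") && !inherits(asm, "error")) {
    extra <- setdiff(unique(asm$chrom), unique(ref$chrom))
    if (length(extra)) {
      note("warning", paste("assembly chromosomes absent from reference:",
                            paste(extra, collapse = ", ")))
    }
  }
  if (!inherits(counts, "error") && !inherits(groups, "error")) {
    samples <- setdiff(names(counts), "feature_id")
    missing <- setdiff(samples, groups$sample)
    if (length(missing)) {
      note("error", paste("samples missing from group sidecar:",
                          paste(missing, collapse = ", ")))
    }
  }
  if (length(probs)) bind_rows(probs) else tibble(level = character(), message = character())
}

#' @noRd
stage_log <- function(stage, msg) {
  inform(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate (optional), discover,
#' quantify, de, integrate, enrich — writing a TSV per result into `outdir`
#' and logging row counts per stage. Re-running with the same configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list: `manifest` (tibble `file`, `n_rows`, `md5`),
#'   `results` (the in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lnc_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  issues <- validate_inputs(config)
  if (any(issues$level == "error")) {
    abort(paste0("input validation failed:\n",
                 paste("-", issues$message[issues$level == "error"], collapse = "\n")))
  }
  for (m in issues$message[issues$level == "warning"]) warn(m)

  paths <- config$paths
  res <- list()
  outputs <- list()
  keep <- function(name, tbl) {
    path <- file.path(config$outdir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, path)
    outputs[[name]] <<- path
    tbl
  }

  if ("simulate" %in% config$stages && isTRUE(config$simulate)) {
    ds <- simulate_dataset(config$sim, dir = file.path(config$outdir, "inputs"))
    paths <- as.list(ds$files[c("reference_gtf", "assembly_gtf", "transcripts_fa",
                                "counts_tsv", "groups_tsv", "lengths_tsv",
                                "precursors_fa", "gene_sets_gmt")])
    res$sim <- ds
    stage_log("simulate", sprintf("%d candidates, %d features",
                                  dplyr::n_distinct(ds$candidates$transcript_id),
                                  nrow(ds$counts)))
  }

  reference <- read_gtf(paths$reference_gtf)
  candidates <- read_gtf(paths$assembly_gtf)
  seqs <- read_fasta(paths$transcripts_fa)

  # discover
  disc <- discover_lncrnas(candidates, reference, seqs,
                           min_len = config$min_len, orf_min = config$orf_min,
                           fickett_cut = config$fickett_cut,
                           cov_min = config$cov_min)
  keep("filter_table", disc$filter)
  keep("coding_potential", disc$scores)
  keep("lncrnas", disc$lncrnas)
  keep("class_counts", disc$class_counts)
  res$discover <- disc
  stage_log("discover", sprintf("%d candidates in, %d lncRNAs out",
                                nrow(disc$filter), nrow(disc$lncrnas)))

  # quantify
  counts <- readr::read_tsv(paths$counts_tsv, show_col_types = FALSE)
  groups <- readr::read_tsv(paths$groups_tsv, show_col_types = FALSE)
  lengths <- readr::read_tsv(paths$lengths_tsv, show_col_types = FALSE)
  fpkm <- keep("fpkm", compute_fpkm(counts, lengths))
  keep("sample_correlation", sample_correlation(fpkm))
  kinds <- tibble(feature_id = counts$feature_id,
                  kind = ifelse(counts$feature_id %in% disc$lncrnas$transcript_id,
                                "lncRNA", "mRNA"))
  summ <- expression_summaries(fpkm, kinds)
  keep("expression_density", summ$density)
  keep("expression_per_kind", summ$per_kind)
  res$quantify <- list(fpkm = fpkm, kinds = kinds, summaries = summ)
  stage_log("quantify", sprintf("%d features x %d samples",
                                nrow(fpkm), ncol(fpkm) - 1))

  # de: mRNAs and lncRNAs called separately
  de_all <- de_test(counts, groups, lengths, method = config$de_method,
                    pseudocount = config$pseudocount)
  is_lnc <- de_all$feature_id %in% disc$lncrnas$transcript_id
  dem <- call_de(de_all[!is_lnc, ], fc_cut = config$fc_cut, q_cut = config$q_cut)
  del <- call_de(de_all[is_lnc, ], fc_cut = config$fc_cut, q_cut = config$q_cut)
  keep("de_mrna", dem$table)
  keep("de_lncrna", del$table)
  keep("de_summary", bind_rows(mutate(glance(dem), kind = "mRNA"),
                               mutate(glance(del), kind = "lncRNA")))
  res$de <- list(dem = dem, del = del)
  stage_log("de", sprintf("%d DEMs, %d DELs",
                          length(de_features(dem)), length(de_features(del))))

  # integrate
  del_ids <- de_features(del)
  del_exons <- filter(candidates, .data$transcript_id %in% del_ids)
  cis <- predict_cis_targets(del_exons, reference, window = config$window)
  keep("cis_pairs", cis)
  scan <- precursor_scan(seqs[intersect(del_ids, names(seqs))],
                         read_fasta(paths$precursors_fa),
                         min_identity = config$min_identity,
                         min_coverage = config$min_coverage)
  keep("precursor_hits", scan$hits)
  net <- build_core_network(cis, del, dem)
  keep("network_edges", net$edges)
  keep("network_summary", net$summary)
  res$integrate <- list(cis = cis, scan = scan, network = net)
  stage_log("integrate", sprintf("%d cis pairs, %d precursor DELs, %d edges",
                                 nrow(cis), scan$n_dels_with_hit,
                                 nrow(net$edges)))

  # enrich
  terms <- read_gmt(paths$gene_sets_gmt)
  background <- dem$table$feature_id
  deg <- intersect(de_features(dem), background)
  enr_deg <- hypergeom_enrich(deg, background, terms)
  keep("enrichment_deg", enr_deg$table)
  keep("enrichment_deg_top", top_terms(enr_deg, k = config$top_k))
  cis_targets <- intersect(unique(cis$gene_id), background)
  enr_cis <- hypergeom_enrich(cis_targets, background, terms)
  keep("enrichment_cis_targets", enr_cis$table)
  keep("enrichment_cis_targets_top", top_terms(enr_cis, k = config$top_k))
  res$enrich <- list(deg = enr_deg, cis_targets = enr_cis)
  stage_log("enrich", sprintf("%d terms tested", nrow(enr_deg$table)))

  manifest <- tibble(
    file = unname(unlist(outputs)),
    n_rows = vapply(names(outputs), function(n) {
      length(readr::read_lines(outputs[[n]])) - 1L
    }, integer(1)),
    md5 = unname(tools::md5sum(unlist(outputs)))
  )
  readr::write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  invisible(list(manifest = manifest, results = res))
}
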
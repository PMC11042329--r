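## End-to-end orchestration: simulate -> psup -> scores -> fit -> translation
## -> coloc from a single config, with per-stage seeds derived from the
## global seed and a JSON manifest of products.

#' Default demonstration pipeline configuration
#'
#' A compact synthetic run: a control and one condensation-inducing condition,
#' pSup inference, condensation scores, model fits with the nested F-test,
#' a spike-in polysome experiment, and a two-condition colocalization field.
#'
#' @param seed Global seed.
#' @param outdir Output directory.
#' @return A named list accepted by \code{\link{runPipeline}}.
#' @export
demoConfig <- function(seed = 1L, outdir = tempfile("sedseq_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    stages = c("simulate", "psup", "scores", "fit", "translation", "coloc"),
    simulate = list(n_transcripts = 2000, depth = 2e6, alpha_s = 1.6,
                    alpha_p = 0.6, dispersion = 100, beta = 2e-4, chi = 0.8,
                    mu = 1.5, nu = 0, gene_noise_sd = 0.35,
                    regulon_fractions = c(induced = 0.05),
                    induction_log2fc = c(induced = 3),
                    escape_effect = c(induced = 1.5)),
    translation = list(n_transcripts = 500, spike_set_size = 20),
    coloc = list(n_cells = 30, spots_per_cell = 10, enrichment = 8)
  )
}

.stage_seed <- function(config, stage)
  derive_seed(config$seed, match(stage, c("simulate", "psup", "scores",
                                          "fit", "translation", "coloc")))

#' Run the Sed-seq analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order. Stages communicate only
#' via the documented files under \code{outdir}; a JSON manifest records
#' every product with its MD5 hash, the global and per-stage seeds, and the
#' full configuration. Any stage failure aborts with the failing stage named;
#' files written by earlier stages are retained.
#'
#' @param config A config list (see \code{\link{demoConfig}}) or the path to
#'   a YAML file holding one.
#' @return The manifest (list), invisibly; also written to
#'   \code{outdir/manifest.json}.
#' @export
runPipeline <- function(config = demoConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed) || is.null(config$outdir))
    stop("config must provide 'seed' and 'outdir'", call. = FALSE)
  known <- c("simulate", "psup", "scores", "fit", "translation", "coloc")
  stages <- config$stages
  if (!all(stages %in% known))
    stop("unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "), call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  products <- list()
  add <- function(stage, name, path) {
    products[[length(products) + 1]] <<- list(
      stage = stage, name = name, path = path,
      md5 = unname(tools::md5sum(path)))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  out <- function(...) file.path(config$outdir, ...)

  if ("simulate" %in% stages) run_stage("simulate", function() {
    p <- config$simulate
    seed <- .stage_seed(config, "simulate")
    catalog <- makeCatalog(p$n_transcripts,
                           regulon_fractions = unlist(p$regulon_fractions),
                           seed = seed)
    ctrl <- conditionSpec("control", gene_noise_sd = p$gene_noise_sd)
    trt <- conditionSpec("treated", mu = p$mu, nu = p$nu,
                         induction_log2fc = unlist(p$induction_log2fc),
                         escape_effect = unlist(p$escape_effect),
                         gene_noise_sd = p$gene_noise_sd)
    for (cond in list(ctrl, trt)) {
      ps <- simulateTruePSup(catalog, cond, beta = p$beta, chi = p$chi,
                             seed = derive_seed(seed, nchar(cond$name)))
      fc <- simulateFractionCounts(
        catalog, ps, condition = cond,
        alpha_s = p$alpha_s, alpha_p = p$alpha_p,
        dispersion = p$dispersion, depth = p$depth,
        experiment_id = cond$name,
        seed = derive_seed(seed, 100 + nchar(cond$name)))
      writeCountsTSV(fc, out(paste0("counts_", cond$name, ".tsv")))
      write_tsv(data.frame(transcript_id = names(ps), true_psup = ps),
                out(paste0("truth_", cond$name, ".tsv")))
      add("simulate", paste0("counts_", cond$name),
          out(paste0("counts_", cond$name, ".tsv")))
      add("simulate", paste0("truth_", cond$name),
          out(paste0("truth_", cond$name, ".tsv")))
    }
    write_tsv(catalog, out("catalog.tsv"))
    add("simulate", "catalog", out("catalog.tsv"))
  })

  if ("psup" %in% stages) run_stage("psup", function() {
    for (cond in c("control", "treated")) {
      fc <- readCountsTSV(out(paste0("counts_", cond, ".tsv")), cond)
      ratios <- estimateMixingRatios(fc)
      tab <- computePSup(fc, ratios)
      write_tsv(tab, out(paste0("psup_", cond, ".tsv")))
      add("psup", paste0("psup_", cond), out(paste0("psup_", cond, ".tsv")))
    }
  })

  if ("scores" %in% stages) run_stage("scores", function() {
    ctrl <- read_tsv(out("psup_control.tsv"))
    trt <- read_tsv(out("psup_treated.tsv"))
    sc <- condensationScores(ctrl, trt, condition = "treated")
    write_tsv(sc, out("scores.tsv"))
    add("scores", "scores", out("scores.tsv"))
  })

  if ("fit" %in% stages) run_stage("fit", function() {
    ctrl <- read_tsv(out("psup_control.tsv"))
    trt <- read_tsv(out("psup_treated.tsv"))
    full <- fitStress(ctrl, trt, terms = c("mu", "nu"))
    nu_only <- fitStress(ctrl, trt, terms = "nu")
    ft <- nestedFTest(full, nu_only)
    rep <- list(full = as.list(coef(full)), rss_full = full@rss,
                nu_only = as.list(coef(nu_only)), rss_nu_only = nu_only@rss,
                f_test = ft)
    jsonlite::write_json(rep, out("fit.json"), auto_unbox = TRUE,
                         digits = NA)
    add("fit", "fit", out("fit.json"))
  })

  if ("translation" %in% stages) run_stage("translation", function() {
    p <- config$translation
    seed <- .stage_seed(config, "translation")
    catalog <- makeCatalog(p$n_transcripts, seed = seed)
    occ <- stats::setNames(with_seed(seed, runif(p$n_transcripts)),
                           catalog$transcript_id)
    tab <- simulatePolysome(catalog, occ, spike_set_size = p$spike_set_size,
                            seed = derive_seed(seed, 1))
    norm <- spikeinNormalize(tab)
    occ_est <- ribosomeOccupancy(norm)
    write_tsv(occ_est, out("occupancy.tsv"))
    add("translation", "occupancy", out("occupancy.tsv"))
  })

  if ("coloc" %in% stages) run_stage("coloc", function() {
    p <- config$coloc
    seed <- .stage_seed(config, "coloc")
    fields <- list(null = 0, enriched = p$enrichment)
    per_cell <- do.call(rbind, lapply(names(fields), function(nm) {
      f <- simulateFishField(p$n_cells, p$spots_per_cell,
                             granule_enrichment = fields[[nm]],
                             seed = derive_seed(seed, nchar(nm)))
      writeImageTIFF(f$marker, out(paste0("marker_", nm, ".tiff")))
      writeMaskTIFF(f$mask, out(paste0("mask_", nm, ".tiff")))
      utils::write.csv(f$spots, out(paste0("spots_", nm, ".csv")),
                       row.names = FALSE)
      sc <- colocalizationScores(f$marker, f$mask, f$spots,
                                 seed = derive_seed(seed, 10 + nchar(nm)))
      sc$condition <- nm
      sc
    }))
    utils::write.csv(per_cell, out("coloc_cells.csv"), row.names = FALSE)
    pop <- populationScore(per_cell)
    jsonlite::write_json(
      list(scores = as.list(pop$scores), comparisons = pop$comparisons),
      out("coloc.json"), auto_unbox = TRUE, digits = NA)
    add("coloc", "coloc_cells", out("coloc_cells.csv"))
    add("coloc", "coloc", out("coloc.json"))
  })

  manifest <- list(
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) .stage_seed(config, s)), stages),
    config = config[setdiff(names(config), "outdir")],
    products = products)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
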
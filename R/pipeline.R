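#' Default pipeline configuration
#'
#' Every signal-mining threshold is an explicit, overridable config entry:
#' the Wald multiplier 1.96 is baked into the statistics, and the criteria
#' defaults are `a >= 3`, CI lower limit > 1 (ROR/PRR), `PRR >= 2` with
#' `chi2 >= 4` (MHRA, Yates-corrected by default), and IC - 2 SD > 0 (BCPNN).
#'
#' @param ... overrides of the default entries.
#' @return named list configuration.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_reports = 3363L,
    year_window = c(2016L, 2020L),
    accepted_causality = c("certain", "probable", "possible"),
    chi2 = "yates",
    ic_variant = "n4",
    onset_breaks = DEFAULT_ONSET_BINS,
    onset_labels = DEFAULT_ONSET_LABELS,
    top_signals = 10L)
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

#' Run the full pharmacovigilance pipeline
#'
#' simulate (or load) -> validate -> include/exclude -> expand combinations ->
#' mine signals -> descriptive tables -> risk factors -> off-label flags,
#' writing every artifact plus a reproducibility manifest to `outdir`:
#' `exclusions.csv`, `combinations.csv`, `signals.csv`,
#' `descriptive_report.json`, `risk_factors.csv`, `offlabel_signals.csv`,
#' `run_manifest.json`. Reruns with the same config reproduce identical
#' outputs.
#'
#' @param config list from [pipeline_config()]. If `config$input_dir` is set
#'   the reports are read from that long-format CSV set; otherwise a
#'   synthetic dataset is generated from `config$synthetic` (a
#'   [synthetic_config()]; built from `n_reports` if absent) with
#'   `config$seed`.
#' @param outdir output directory (created).
#' @param dictionaries list from [load_dictionaries()]; when reports are
#'   simulated the generator's roster dictionaries are used by default.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         dictionaries = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$input_dir)) {
      reports <- read_reports(config$input_dir)
      if (is.null(dictionaries)) dictionaries <- load_dictionaries()
      ground_truth <- NULL
    } else {
      syn <- config$synthetic %||% synthetic_config(n_reports = config$n_reports)
      gen <- generate_reports(syn, seed = config$seed)
      reports <- gen$reports
      ground_truth <- gen$ground_truth
      if (is.null(dictionaries))
        dictionaries <- list(drugs = roster_drug_dictionary(syn),
                             terms = roster_term_dictionary(syn),
                             labels = load_dictionaries()$labels)
    }

    stage <- "preprocess"
    incl <- apply_inclusion_exclusion(reports, dictionaries$drugs,
                                      year_window = config$year_window,
                                      accepted_causality = config$accepted_causality)
    utils::write.csv(incl$exclusions, file.path(outdir, "exclusions.csv"),
                     row.names = FALSE)
    combos <- expand_combinations(incl$included, dictionaries$drugs,
                                  dictionaries$terms)
    utils::write.csv(combos, file.path(outdir, "combinations.csv"),
                     row.names = FALSE)

    stage <- "signal"
    signals <- mine_signals(combos, chi2 = config$chi2,
                            ic_variant = config$ic_variant)
    utils::write.csv(signals, file.path(outdir, "signals.csv"),
                     row.names = FALSE)

    stage <- "describe"
    trend <- yearly_trend(incl$included, config$year_window)
    onset <- onset_distribution(incl$included, dictionaries$drugs,
                                breaks = config$onset_breaks,
                                labels = config$onset_labels)
    drug_tab <- drug_seriousness_table(incl$included, dictionaries$drugs)
    socs <- soc_table(combos)
    pts_all <- pt_table(combos)
    outc <- outcome_table(incl$included)
    descriptive <- list(
      yearly_trend = trend,
      onset_distribution = c(list(table = onset),
                             n_missing = attr(onset, "n_missing"),
                             n_negative = attr(onset, "n_negative")),
      drug_seriousness = drug_tab,
      soc = list(table = socs, denominator = attr(socs, "denominator")),
      pt = list(table = pts_all, denominator = attr(pts_all, "denominator")),
      outcomes = list(table = outc, denominator = attr(outc, "denominator")))
    jsonlite::write_json(descriptive, file.path(outdir, "descriptive_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")

    stage <- "riskfactors"
    cov <- derive_covariates(incl$included, dictionaries$drugs)
    rf <- fit_serious_model(cov)
    utils::write.csv(rf$table, file.path(outdir, "risk_factors.csv"),
                     row.names = FALSE)

    stage <- "offlabel"
    ranked <- rank_signals(signals)
    ranked <- flag_offlabel(ranked, dictionaries$labels)
    utils::write.csv(ranked, file.path(outdir, "offlabel_signals.csv"),
                     row.names = FALSE)

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("srsmine")),
      seed = config$seed,
      config = config[setdiff(names(config), "synthetic")],
      counts = list(parsed = n_reports(reports),
                    validation_errors = nrow(validation_errors(reports)),
                    excluded = nrow(incl$exclusions),
                    included = n_reports(incl$included),
                    combinations = nrow(combos),
                    evaluated_pairs = nrow(signals),
                    consensus_signals = sum(signals$flag_consensus),
                    offlabel_signals = sum(ranked$offlabel == "off-label")))
    jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(reports = reports, included = incl$included,
         exclusions = incl$exclusions, combos = combos, signals = signals,
         descriptive = descriptive, risk_factors = rf, ranked = ranked,
         manifest = manifest, ground_truth = ground_truth)
  }, srsmine_error = function(e) {
    writeLines(paste0("INCOMPLETE at stage: ", stage),
               file.path(outdir, "INCOMPLETE"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset + ground truth),
#' `run` (full pipeline). Example:
#' `Rscript -e 'srsmine::srsmine_cli()' run --outdir out --seed 7 --n 5000`.
#'
#' @param args character vector of CLI arguments (default: the command line).
#' @return exit status, invisibly.
#' @export
srsmine_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: srsmine <simulate|run> [--outdir DIR] [--seed N] [--n N]",
    "              [--chi2 yates|pearson] [--ic-variant n4|plain] [--input DIR]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list(outdir = "srsmine_out", seed = 1L, n = 3363L,
              chi2 = "yates", ic_variant = "n4", input = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  opt$seed <- as.integer(opt$seed); opt$n <- as.integer(opt$n)
  if (cmd == "simulate") {
    gen <- generate_reports(synthetic_config(n_reports = opt$n),
                            seed = opt$seed)
    write_reports(gen$reports, opt$outdir)
    gt <- gen$ground_truth
    jsonlite::write_json(list(injected_pairs = gt$injected_pairs,
                              serious_intercept = gt$serious_intercept,
                              serious_coefs = as.list(gt$serious_coefs)),
                         file.path(opt$outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("wrote synthetic dataset to ", opt$outdir)
  } else if (cmd == "run") {
    cfg <- pipeline_config(seed = opt$seed, n_reports = opt$n,
                           chi2 = opt$chi2, ic_variant = opt$ic_variant)
    if (!is.null(opt$input)) cfg$input_dir <- opt$input
    run_pipeline(cfg, outdir = opt$outdir)
    message("pipeline artifacts written to ", opt$outdir)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
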
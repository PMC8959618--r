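TABLE_DRUGS <- data.frame(
  generic_drug = c("risperidone", "clozapine", "olanzapine", "aripiprazole",
                   "quetiapine", "amisulpride", "ziprasidone", "perospirone",
                   "haloperidol", "perphenazine", "sulpiride", "chlorpromazine",
                   "penfluridol", "chlorprothixene", "droperidol"),
  apd_class = c(rep("atypical", 8), rep("typical", 7)),
  n_study = c(1083, 554, 350, 236, 214, 207, 206, 120,
              216, 64, 61, 43, 5, 3, 1))

NON_APD_DRUGS <- c("aspirin", "metformin", "amlodipine", "sertraline",
                   "valproate", "lorazepam")

# 44-PT vocabulary with masses echoing the published frequency profile
# (top terms at their observed combination shares, the tail spread over
# plausible antipsychotic ADRs); weights are normalized at config build time.
BASE_PTS <- data.frame(
  pt = c("Extrapyramidal disorder", "Akathisia", "Constipation", "Drooling",
         "White blood cell count decreased", "Tremor", "Somnolence",
         "Hepatic function abnormal", "Dizziness", "Tachycardia",
         "Nausea", "Vomiting", "Weight increased", "Dystonia",
         "Electrocardiogram QT prolonged", "Headache", "Palpitations",
         "Rash", "Insomnia", "Pyrexia", "Fatigue", "Vision blurred",
         "Blood glucose increased", "Agitation", "Anxiety", "Dry mouth",
         "Hypertonia", "Orthostatic hypotension", "Pruritus", "Hypotension",
         "Muscle rigidity", "Blood pressure decreased", "Hyperprolactinaemia",
         "Dyspnoea", "Abnormal sensation in eye", "Sinus bradycardia",
         "Dysphagia", "Obesity", "Pollakiuria", "Urinary incontinence",
         "Amenorrhoea", "Galactorrhoea", "Tongue induration",
         "Nuchal rigidity"),
  soc = c("Nervous system disorders", "Nervous system disorders",
          "Gastrointestinal disorders", "Gastrointestinal disorders",
          "Investigations", "Nervous system disorders",
          "Nervous system disorders", "Hepatobiliary disorders",
          "Nervous system disorders", "Cardiac disorders",
          "Gastrointestinal disorders", "Gastrointestinal disorders",
          "Investigations", "Nervous system disorders", "Investigations",
          "Nervous system disorders", "Cardiac disorders",
          "Skin and subcutaneous tissue disorders", "Psychiatric disorders",
          "General disorders and administration site conditions",
          "General disorders and administration site conditions",
          "Eye disorders", "Investigations", "Psychiatric disorders",
          "Psychiatric disorders", "Gastrointestinal disorders",
          "Nervous system disorders", "Vascular disorders",
          "Skin and subcutaneous tissue disorders", "Vascular disorders",
          "Musculoskeletal and connective tissue disorders", "Investigations",
          "Endocrine disorders", "Respiratory, thoracic and mediastinal disorders",
          "Eye disorders", "Cardiac disorders", "Gastrointestinal disorders",
          "Metabolism and nutrition disorders", "Renal and urinary disorders",
          "Renal and urinary disorders",
          "Reproductive system and breast disorders",
          "Reproductive system and breast disorders",
          "Gastrointestinal disorders",
          "Musculoskeletal and connective tissue disorders"),
  weight = c(0.2396, 0.0594, 0.0501, 0.0395, 0.0385, 0.0314, 0.0210,
             0.0202, 0.0200, 0.0190, 0.0400, 0.0300, 0.0300, 0.0300,
             0.0200, 0.0200, 0.0200, 0.0150, 0.0150, 0.0150, 0.0150,
             0.0150, 0.0150, 0.0120, 0.0120, 0.0120, 0.0120, 0.0120,
             0.0120, 0.0100, 0.0100, 0.0100, 0.0100, 0.0080, 0.0080,
             0.0080, 0.0080, 0.0060, 0.0050, 0.0050, 0.0080, 0.0050,
             0.0040, 0.0040))

DEFAULT_INJECTED <- data.frame(
  generic_drug = c("perphenazine", "sulpiride", "chlorpromazine",
                   "chlorpromazine", "haloperidol", "olanzapine",
                   "amisulpride", "ziprasidone", "quetiapine", "olanzapine"),
  pt = c("Tongue induration", "Insomnia", "Blood pressure decreased",
         "Orthostatic hypotension", "Dystonia", "Obesity", "Pollakiuria",
         "Dyspnoea", "Urinary incontinence", "Hepatic function abnormal"),
  rr = c(8, 8, 7, 7, 5, 6, 6, 5, 5, 4))

# log odds ratios of the published serious-ADR risk-factor model
DEFAULT_SERIOUS_COEFS <- c(
  "sex:female" = log(1.25),
  "age_bin:<18" = log(1.59), "age_bin:35-65" = log(0.98),
  "age_bin:>=65" = log(2.17),
  "season:summer" = log(0.95), "season:autumn" = log(1.26),
  "season:winter" = log(1.31),
  "apd_class:atypical" = log(1.55),
  "hospital_level:2" = log(0.41), "hospital_level:3" = log(0.37),
  "hospital_type:psychiatric" = log(2.61),
  "multiple_disease:TRUE" = log(1.67),
  "polypharmacy:TRUE" = log(0.92))

#' Configuration of the synthetic SRS generator
#'
#' Defaults describe a "study-like" world: the 15 antipsychotics at their
#' published report shares, a 44-PT reaction vocabulary with published-profile
#' masses, reports rising year by year over 2016-2020, ~1.18 drug-event
#' combinations per report, onset delays log-normal with median 20 days
#' (most within 3 months), outcome and causality mixes matching the study,
#' covariate-driven seriousness at the study's log odds ratios with an
#' intercept calibrated to the ~9% marginal serious rate, and ten injected
#' disproportionality pairs with reporting-rate ratios 4-8.
#'
#' @param n_reports number of reports to generate.
#' @param years calendar years and `year_weights` their sampling weights.
#' @param year_weights see `years`.
#' @param drugs data.frame `generic_drug, apd_class, freq` of the suspected
#'   antipsychotic roster (freq normalized internally).
#' @param p_nonapd_suspected probability a report's suspected drug is a
#'   non-antipsychotic (such reports exercise the exclusion path).
#' @param concomitant_probs probabilities of 0..k concomitant drugs.
#' @param n_reactions_probs probabilities of 1..5 reaction terms per report.
#' @param pts data.frame `pt, soc, weight` — the baseline reaction vocabulary.
#' @param injected_pairs data.frame `generic_drug, pt, rr` with `rr >= 1`:
#'   for a report whose suspected drug is in a pair, that PT's sampling
#'   weight is multiplied by `rr` and the vector renormalized.
#' @param serious_intercept,serious_coefs logit intercept and named log-OR
#'   vector driving the Bernoulli serious flag.
#' @param sex_probs named probabilities over male/female/unknown.
#' @param age_mean,age_sd,age_range truncated-normal age model (years).
#' @param p_age_missing probability age is missing.
#' @param hospital_level_probs probabilities of levels 1..3.
#' @param p_psychiatric probability the reporting hospital is psychiatric.
#' @param p_multiple_disease probability of a second diagnosis.
#' @param onset_meanlog,onset_sdlog log-normal onset-delay parameters (days).
#' @param outcome_probs,causality_probs named category probabilities.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_reports = 3363,
    years = 2016:2020,
    year_weights = c(0.10, 0.15, 0.20, 0.25, 0.30),
    drugs = data.frame(generic_drug = TABLE_DRUGS$generic_drug,
                       apd_class = TABLE_DRUGS$apd_class,
                       freq = TABLE_DRUGS$n_study / sum(TABLE_DRUGS$n_study)),
    p_nonapd_suspected = 0.02,
    concomitant_probs = c(0.55, 0.25, 0.13, 0.07),
    n_reactions_probs = c(0.855, 0.12, 0.02, 0.004, 0.001),
    pts = BASE_PTS,
    injected_pairs = DEFAULT_INJECTED,
    serious_intercept = -2.9606,
    serious_coefs = DEFAULT_SERIOUS_COEFS,
    sex_probs = c(male = 0.5212, female = 0.4738, unknown = 0.005),
    age_mean = 33.29, age_sd = 16.651, age_range = c(1, 94),
    p_age_missing = 0.005,
    hospital_level_probs = c(0.08, 0.32, 0.60),
    p_psychiatric = 0.75,
    p_multiple_disease = 0.02,
    onset_meanlog = log(20), onset_sdlog = 1.1,
    outcome_probs = c(cured = 0.7710, relieved = 0.1745,
                      not_relieved = 0.0217, sequelae = 0.0003,
                      missing = 0.0325),
    causality_probs = c(certain = 0.05, probable = 0.45, possible = 0.48,
                        unlikely = 0.015, impossible = 0.005)) {
  cfg <- as.list(environment())
  for (nm in c("year_weights", "concomitant_probs", "n_reactions_probs",
               "sex_probs", "hospital_level_probs", "outcome_probs",
               "causality_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_srs(nm, " must be a probability vector summing to 1",
               class = "srs_config")
  }
  if (abs(sum(cfg$pts$weight) - 1) > 1e-2) cfg$pts$weight <-
    cfg$pts$weight / sum(cfg$pts$weight)
  cfg$pts$weight <- cfg$pts$weight / sum(cfg$pts$weight)
  cfg$drugs$freq <- cfg$drugs$freq / sum(cfg$drugs$freq)
  if (nrow(cfg$injected_pairs)) {
    if (any(cfg$injected_pairs$rr < 1))
      stop_srs("injected rr must be >= 1", class = "srs_config")
    if (!all(cfg$injected_pairs$generic_drug %in% cfg$drugs$generic_drug) ||
        !all(cfg$injected_pairs$pt %in% cfg$pts$pt))
      stop_srs("injected pair references unknown drug or PT",
               class = "srs_config")
  }
  stopifnot(length(cfg$years) == length(cfg$year_weights))
  structure(cfg, class = "synthetic_config")
}

# per-drug PT sampling weights after multiplicative injection + renormalize
.drug_pt_weights <- function(config, drug) {
  w <- config$pts$weight
  inj <- config$injected_pairs
  if (nrow(inj)) {
    hit <- inj[inj$generic_drug == drug, , drop = FALSE]
    if (nrow(hit)) w[match(hit$pt, config$pts$pt)] <-
        w[match(hit$pt, config$pts$pt)] * hit$rr
  }
  w / sum(w)
}

rtnorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a synthetic SRS dataset with known ground truth
#'
#' Samples reports under the generative model of [synthetic_config()]:
#' covariates are drawn from their marginals, one suspected drug per report
#' from the roster frequencies, 1-5 reaction PTs from the baseline vocabulary
#' reweighted by `rr` for injected (drug, PT) pairs, and the serious flag
#' from a Bernoulli with logit linear in the report's covariates. Identical
#' `config` and `seed` yield identical datasets.
#'
#' @param config a `synthetic_config`.
#' @param seed integer RNG seed (mandatory: datasets must be reproducible).
#' @return list: `reports` (an `srs_reports`) and `ground_truth` (list with
#'   `injected_pairs`, `serious_intercept`, `serious_coefs`, and the config).
#' @export
generate_reports <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"), !missing(seed))
  set.seed(as.integer(seed))
  n <- config$n_reports
  id <- sprintf("R%07d", seq_len(n))

  year <- sample_cat(n, config$years, config$year_weights)
  month <- sample.int(12, n, replace = TRUE)
  day <- sample.int(28, n, replace = TRUE)
  report_date <- as.Date(sprintf("%d-%02d-%02d", year, month, day))
  sex <- sample_cat(n, names(config$sex_probs), config$sex_probs)
  age <- round(rtnorm(n, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2]))
  age[runif(n) < config$p_age_missing] <- NA
  lvl <- sample_cat(n, 1:3, config$hospital_level_probs)
  htype <- ifelse(runif(n) < config$p_psychiatric, "psychiatric", "general")
  multi_dx <- runif(n) < config$p_multiple_disease
  diagnoses <- ifelse(multi_dx, "schizophrenia;hypertension", "schizophrenia")
  causality <- sample_cat(n, names(config$causality_probs), config$causality_probs)
  outcome <- sample_cat(n, names(config$outcome_probs), config$outcome_probs)

  # suspected drug (one per report; a small share are non-antipsychotics)
  nonapd <- runif(n) < config$p_nonapd_suspected
  drug <- sample_cat(n, config$drugs$generic_drug, config$drugs$freq)
  drug[nonapd] <- sample(NON_APD_DRUGS, sum(nonapd), replace = TRUE)
  apd_class <- config$drugs$apd_class[match(drug, config$drugs$generic_drug)]
  apd_class[nonapd] <- "non_apd"

  n_conc <- sample_cat(n, seq_along(config$concomitant_probs) - 1L,
                       config$concomitant_probs)
  polypharmacy <- (1L + n_conc) >= 3L

  # reactions: per-slot PT sampling conditioned on the suspected drug
  k <- sample_cat(n, seq_along(config$n_reactions_probs),
                  config$n_reactions_probs)
  slot_rep <- rep(seq_len(n), k)
  slot_drug <- drug[slot_rep]
  pt <- character(length(slot_rep))
  for (g in unique(slot_drug)) {
    i <- which(slot_drug == g)
    w <- if (g %in% config$drugs$generic_drug) .drug_pt_weights(config, g)
         else config$pts$weight
    pt[i] <- sample_cat(length(i), config$pts$pt, w)
  }
  rxn <- unique(data.table(report_id = id[slot_rep], raw_term = pt))

  # seriousness from the covariate-driven logit
  eta <- rep(config$serious_intercept, n)
  cf <- config$serious_coefs
  add <- function(name, ind) if (name %in% names(cf)) eta <<- eta + cf[[name]] * ind
  add("sex:female", sex == "female")
  ab <- as.character(bin_age(age)); ab[is.na(ab)] <- "18-35"  # missing age: reference risk
  add("age_bin:<18", ab == "<18"); add("age_bin:35-65", ab == "35-65")
  add("age_bin:>=65", ab == ">=65")
  season <- month_to_season(month)
  add("season:summer", season == "summer"); add("season:autumn", season == "autumn")
  add("season:winter", season == "winter")
  add("apd_class:atypical", apd_class == "atypical")
  add("hospital_level:2", lvl == 2); add("hospital_level:3", lvl == 3)
  add("hospital_type:psychiatric", htype == "psychiatric")
  add("multiple_disease:TRUE", multi_dx)
  add("polypharmacy:TRUE", polypharmacy)
  serious <- runif(n) < plogis(eta)

  delay <- pmax(0, round(rlnorm(n, config$onset_meanlog, config$onset_sdlog)))
  start_date <- report_date - delay
  rxn$onset_date <- report_date[match(rxn$report_id, id)]

  drugs_tab <- data.frame(report_id = id, raw_name = drug, role = "suspected",
                          start_date = start_date)
  if (any(n_conc > 0)) {
    conc_rep <- rep(seq_len(n), n_conc)
    conc <- data.frame(report_id = id[conc_rep],
                       raw_name = sample(NON_APD_DRUGS, length(conc_rep),
                                         replace = TRUE),
                       role = "concomitant",
                       start_date = start_date[conc_rep])
    drugs_tab <- rbind(drugs_tab, conc)
  }
  drugs_tab <- drugs_tab[order(match(drugs_tab$report_id, id)), ]
  rownames(drugs_tab) <- NULL

  reports <- data.frame(report_id = id, sex = sex, age = age,
                        report_date = report_date, hospital_level = lvl,
                        hospital_type = htype, diagnoses = diagnoses,
                        causality = causality, serious = serious,
                        outcome = outcome, date_imputed = FALSE)
  reactions <- setDF(as.data.frame(rxn[order(match(rxn$report_id, id))]))
  reactions$onset_imputed <- FALSE

  list(reports = srs_reports(reports, drugs_tab, reactions),
       ground_truth = structure(
         list(injected_pairs = config$injected_pairs,
              serious_intercept = config$serious_intercept,
              serious_coefs = config$serious_coefs,
              config = config),
         class = "srs_ground_truth"))
}

#' Analytic expected fourfold table under the generative model
#'
#' Closed-form expected cell counts for a (drug, PT) pair, the oracle for
#' recovery tests. With `f(g)` the drug share, `q_g(p)` the renormalized
#' per-drug PT weight, and `K` the reactions-per-report count, the expected
#' number of combinations a report contributes for `(g, p)` is
#' `f(g) * E[1 - (1 - q_g(p))^K]` (PTs are drawn with replacement and
#' deduplicated). Cells scale linearly in `n_reports`, and an `rr = 1` pair
#' satisfies `ad = bc` up to the shared renormalization.
#'
#' @param config a `synthetic_config`.
#' @param drug,pt the target pair (must exist in the config rosters).
#' @return list `a, b, c, d, n` of expected (non-integer) counts.
#' @export
expected_table <- function(config, drug, pt) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!drug %in% config$drugs$generic_drug)
    stop_srs("unknown drug: ", drug, class = "srs_config")
  if (!pt %in% config$pts$pt)
    stop_srs("unknown PT: ", pt, class = "srs_config")
  p_inc <- sum(config$causality_probs[c("certain", "probable", "possible")]) *
    (1 - config$p_nonapd_suspected)
  n_eff <- config$n_reports * p_inc
  kp <- config$n_reactions_probs
  ks <- seq_along(kp)
  e_dist <- function(q) sum(kp * (1 - (1 - q)^ks))  # E[#distinct draws of a PT]
  f <- config$drugs$freq
  names(f) <- config$drugs$generic_drug
  pt_i <- match(pt, config$pts$pt)
  ea <- eab <- eac <- en <- 0
  for (g in config$drugs$generic_drug) {
    q <- .drug_pt_weights(config, g)
    e_each <- vapply(q, e_dist, numeric(1))
    contrib <- n_eff * f[[g]]
    en <- en + contrib * sum(e_each)
    eac <- eac + contrib * e_each[pt_i]
    if (g == drug) { ea <- contrib * e_each[pt_i]; eab <- contrib * sum(e_each) }
  }
  list(a = ea, b = eab - ea, c = eac - ea, d = en - eab - eac + ea, n = en)
}

#' Calibrate the seriousness intercept to a target marginal rate
#'
#' Draws a large Monte Carlo sample of covariate linear predictors under the
#' config's marginals and solves for the intercept giving the requested mean
#' serious probability. The shipped default intercept (-2.9606) was fixed this
#' way for a 9% marginal rate, the regime of the source SRS study.
#'
#' @param config a `synthetic_config`.
#' @param target desired marginal serious fraction (default 0.09).
#' @param n_mc Monte Carlo sample size.
#' @param seed RNG seed for the covariate draw.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_serious_intercept <- function(config, target = 0.09,
                                        n_mc = 200000, seed = 20160101) {
  cfg <- config; cfg$n_reports <- n_mc
  cfg$serious_intercept <- 0
  gen <- generate_reports(cfg, seed = seed)
  # reuse the generator's own covariates; eta0 = logit minus intercept
  cov <- derive_covariates(gen$reports, .roster_dictionary(cfg))
  cov$age_bin <- as.character(cov$age_bin)
  cov$age_bin[is.na(cov$age_bin)] <- "18-35"
  cov$apd_class[is.na(cov$apd_class)] <- "typical"
  eta0 <- rep(0, nrow(cov))
  cf <- config$serious_coefs
  for (nm in names(cf)) {
    v <- strsplit(nm, ":", fixed = TRUE)[[1]]
    eta0 <- eta0 + cf[[nm]] * (as.character(cov[[v[1]]]) == v[2])
  }
  uniroot(function(b0) mean(plogis(b0 + eta0)) - target,
          interval = c(-10, 2), tol = 1e-6)$root
}

# in-memory drug dictionary covering the synthetic roster (internal)
.roster_dictionary <- function(config) {
  atc <- c(risperidone = "N05AX08", clozapine = "N05AH02",
           olanzapine = "N05AH03", aripiprazole = "N05AX12",
           quetiapine = "N05AH04", amisulpride = "N05AL05",
           ziprasidone = "N05AE04", perospirone = "N05AX21",
           haloperidol = "N05AD01", perphenazine = "N05AB03",
           sulpiride = "N05AL01", chlorpromazine = "N05AA01",
           penfluridol = "N05AG03", chlorprothixene = "N05AF03",
           droperidol = "N05AD08")
  d <- data.frame(
    key = normalize_key(c(config$drugs$generic_drug, NON_APD_DRUGS)),
    generic_name = c(config$drugs$generic_drug, NON_APD_DRUGS),
    atc_code = c(unname(atc[config$drugs$generic_drug]), rep("", length(NON_APD_DRUGS))),
    apd_class = c(config$drugs$apd_class, rep("non_apd", length(NON_APD_DRUGS))))
  d$atc_code[is.na(d$atc_code)] <- ""
  structure(d, class = c("drug_dictionary", "data.frame"))
}

#' In-memory term dictionary for a synthetic config's PT vocabulary
#'
#' Identity mapping raw term -> (PT, SOC) over the config's vocabulary, for
#' analyses of generated data without CSV round-trips.
#'
#' @param config a `synthetic_config`.
#' @return a `term_dictionary`.
#' @export
roster_term_dictionary <- function(config) {
  structure(data.frame(key = normalize_key(config$pts$pt),
                       pt = config$pts$pt, soc = config$pts$soc),
            class = c("term_dictionary", "data.frame"))
}

#' In-memory drug dictionary for a synthetic config's roster
#'
#' @param config a `synthetic_config`.
#' @return a `drug_dictionary` covering the antipsychotic roster and the
#'   non-antipsychotic fillers the generator uses.
#' @export
roster_drug_dictionary <- function(config) .roster_dictionary(config)
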
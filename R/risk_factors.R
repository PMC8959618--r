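RISK_FACTORS <- list(
  sex              = list(levels = c("male", "female"), ref = "male"),
  age_bin          = list(levels = c("18-35", "<18", "35-65", ">=65"), ref = "18-35"),
  season           = list(levels = c("spring", "summer", "autumn", "winter"), ref = "spring"),
  apd_class        = list(levels = c("typical", "atypical"), ref = "typical"),
  hospital_level   = list(levels = c("1", "2", "3"), ref = "1"),
  hospital_type    = list(levels = c("general", "psychiatric"), ref = "general"),
  multiple_disease = list(levels = c("FALSE", "TRUE"), ref = "FALSE"),
  polypharmacy     = list(levels = c("FALSE", "TRUE"), ref = "FALSE"))

#' Build the dummy-coded design matrix for the serious-ADR model
#'
#' Reference levels: male sex, age 18-35, spring, typical class, hospital
#' level 1, general hospital, single disease, non-polypharmacy. Records with
#' any missing modeled covariate are excluded (complete-case analysis) and
#' counted; a factor observed at a single level is dropped with a warning.
#'
#' @param covariates per-report covariates from [derive_covariates()].
#' @return list: `X` (0/1 design matrix, no intercept column), `y` (logical
#'   serious outcome), `n_excluded` (missing-covariate exclusions),
#'   `dropped_factors`.
#' @export
encode_design <- function(covariates) {
  cc <- covariates
  vars <- names(RISK_FACTORS)
  stopifnot(all(vars %in% names(cc)), "serious" %in% names(cc))
  for (v in vars) cc[[v]] <- as.character(cc[[v]])
  cc$sex[cc$sex == "unknown"] <- NA  # unknown sex: missing for modeling
  keep <- !Reduce(`|`, lapply(cc[vars], is.na)) & !is.na(cc$serious)
  cc <- cc[keep, , drop = FALSE]
  cols <- list(); dropped <- character()
  for (v in vars) {
    spec_v <- RISK_FACTORS[[v]]
    bad <- setdiff(unique(cc[[v]]), spec_v$levels)
    if (length(bad))
      stop_srs("unexpected level(s) in ", v, ": ", paste(bad, collapse = ", "),
               class = "srs_model")
    if (length(unique(cc[[v]])) < 2) {
      warning("factor '", v, "' has a single observed level; dropped")
      dropped <- c(dropped, v); next
    }
    for (lev in setdiff(spec_v$levels, spec_v$ref))
      cols[[paste0(v, ":", lev)]] <- as.integer(cc[[v]] == lev)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  list(X = X, y = cc$serious, n_excluded = sum(!keep), dropped_factors = dropped)
}

#' Fit the logistic risk-factor model for serious reactions
#'
#' Maximum-likelihood logistic regression of the serious flag on the
#' dummy-coded report covariates; the unit of analysis is the report, never
#' the drug-event combination. Adjusted OR = exp(coefficient), 95% CI =
#' exp(coefficient +/- 1.96 SE), p = two-tailed Wald. A per-factor
#' likelihood-ratio test is also reported, since multi-level factors are
#' often summarized by an overall test.
#'
#' @param covariates per-report covariates from [derive_covariates()], or a
#'   design list from [encode_design()].
#' @return `risk_factor_fit`: list with `table` (data.frame `variable, level,
#'   estimate, se, or, ci_lo, ci_hi, p`), `lrt` (per-factor data.frame),
#'   `n_used`, `n_excluded`, `converged`.
#' @export
fit_serious_model <- function(covariates) {
  des <- if (is.list(covariates) && !is.data.frame(covariates) &&
             all(c("X", "y") %in% names(covariates))) covariates
         else encode_design(covariates)
  y <- des$y
  if (length(unique(y)) < 2)
    stop_srs("outcome has a single class; cannot fit", class = "srs_model")
  df <- data.frame(.y = as.integer(y), des$X, check.names = FALSE)
  fit <- glm(.y ~ ., data = df, family = binomial())
  if (!fit$converged)
    stop_srs("logistic fit did not converge", class = "srs_model")
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  names(est) <- gsub("`", "", names(est), fixed = TRUE)
  if (any(is.na(est)))
    stop_srs("design is rank-deficient for: ",
             paste(names(est)[is.na(est)], collapse = ", "), class = "srs_model")
  vl <- strsplit(names(est), ":", fixed = TRUE)
  tab <- data.frame(
    variable = vapply(vl, `[`, "", 1L),
    level = vapply(vl, `[`, "", 2L),
    estimate = unname(est), se = unname(se),
    or = unname(exp(est)),
    ci_lo = unname(exp(est - 1.96 * se)),
    ci_hi = unname(exp(est + 1.96 * se)),
    p = unname(2 * stats::pnorm(-abs(est / se))))
  lrt <- do.call(rbind, lapply(unique(tab$variable), function(v) {
    drop_cols <- paste0(v, ":", tab$level[tab$variable == v])
    df0 <- df[, !(names(df) %in% drop_cols), drop = FALSE]
    fit0 <- glm(.y ~ ., data = df0, family = binomial())
    dev <- fit0$deviance - fit$deviance
    k <- length(drop_cols)
    data.frame(variable = v, lr_chi2 = dev, df = k,
               p = pchisq(dev, k, lower.tail = FALSE))
  }))
  structure(list(table = tab, lrt = lrt, n_used = length(y),
                 n_excluded = des$n_excluded %||% 0L,
                 dropped_factors = des$dropped_factors %||% character(),
                 converged = fit$converged),
            class = "risk_factor_fit")
}

#' @export
print.risk_factor_fit <- function(x, ...) {
  cat(sprintf("Logistic serious-ADR model: n = %d (%d excluded for missing covariates)\n",
              x$n_used, x$n_excluded))
  tab <- x$table
  tab$or <- round(tab$or, 2)
  tab$ci <- sprintf("(%.3f, %.3f)", tab$ci_lo, tab$ci_hi)
  tab$p <- signif(tab$p, 3)
  print(tab[, c("variable", "level", "p", "or", "ci")], row.names = FALSE)
  invisible(x)
}
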
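#' Fourfold (2x2) contingency table for a drug-event pair
#'
#' Cells partition the set of drug-event combinations: `a` = target drug &
#' target reaction, `b` = target drug & other reactions, `c` = other drugs &
#' target reaction, `d` = other drugs & other reactions, `n = a+b+c+d`.
#' Note that `n` counts combinations, not reports.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `contingency_table` object (named list with `n`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop_srs("cells must be non-negative integers", class = "srs_table")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2> a=%d b=%d c=%d d=%d (n=%d)\n", x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Build the fourfold table for one (drug, PT) pair
#'
#' @param combos combination data.frame from [expand_combinations()] (or any
#'   data.frame with `generic_drug` and `pt` columns, one row per combination).
#' @param drug,pt the target pair; a pair absent from the data yields `a = 0`
#'   with valid marginals, not an error.
#' @return a `contingency_table`.
#' @export
build_table <- function(combos, drug, pt) {
  is_d <- combos$generic_drug == drug
  is_p <- combos$pt == pt
  contingency_table(sum(is_d & is_p), sum(is_d & !is_p),
                    sum(!is_d & is_p), sum(!is_d & !is_p))
}

# vectorized cores: all take equal-length numeric a, b, c, d --------------

.ror_core <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- se <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] / c[ok]) / (b[ok] / d[ok])
  se[ok] <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  list(est = ror, li = exp(log(ror) - 1.96 * se), ui = exp(log(ror) + 1.96 * se))
}

.prr_core <- function(a, b, c, d) {
  ok <- a > 0 & (a + b) > 0 & c > 0 & (c + d) > 0
  prr <- se <- rep(NA_real_, length(a))
  prr[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))
  se[ok] <- sqrt(1 / a[ok] - 1 / (a[ok] + b[ok]) + 1 / c[ok] - 1 / (c[ok] + d[ok]))
  list(est = prr, li = exp(log(prr) - 1.96 * se), ui = exp(log(prr) + 1.96 * se))
}

.chi2_core <- function(a, b, c, d, corrected) {
  # doubles throughout: the denominator overflows 32-bit integers easily
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ok <- den > 0
  num <- if (corrected) pmax(0, abs(a * d - b * c) - n / 2)^2 else (a * d - b * c)^2
  out <- rep(NA_real_, length(a))
  out[ok] <- n[ok] * num[ok] / den[ok]
  out
}

.bcpnn_core <- function(a, b, c, d, variant = c("n4", "plain")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  eic <- if (variant == "n4") {
    log2((a + 1) * (n + 2)^2 / ((n + 4) * (a + b + 1) * (a + c + 1)))
  } else {
    log2((a + 1) * (n + 2) / ((a + b + 1) * (a + c + 1)))
  }
  vic <- (1 / log(2)^2) *
    ((n - a + 3) / ((a + 1) * (n + 5)) +
     (n - (a + b) + 1) / ((a + b + 1) * (n + 3)) +
     (n - (a + c) + 1) / ((a + c + 1) * (n + 3)))
  eic[n <= 0] <- NA_real_; vic[n <= 0] <- NA_real_
  list(eic = eic, vic = vic, li = eic - 2 * sqrt(vic), ui = eic + 2 * sqrt(vic))
}

#' Reporting odds ratio with 95% Wald CI
#'
#' `ROR = (a/c)/(b/d)`, `SE(lnROR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `CI = exp(ln ROR +/- 1.96 SE)`. Any zero cell makes the ROR
#' non-computable: the result carries `NA`s and a `reason`, never infinity,
#' and such a pair can never be flagged.
#'
#' @param tab a `contingency_table`.
#' @return list `est, li, ui` (plus `reason` when non-computable).
#' @export
ror_stats <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  r <- .ror_core(tab$a, tab$b, tab$c, tab$d)
  out <- list(est = r$est, li = r$li, ui = r$ui)
  if (is.na(r$est)) out$reason <- "zero cell: ROR undefined"
  out
}

#' Proportional reporting ratio with 95% Wald CI
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`,
#' `SE(lnPRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @inheritParams ror_stats
#' @return list `est, li, ui` (plus `reason` when non-computable).
#' @export
prr_stats <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  r <- .prr_core(tab$a, tab$b, tab$c, tab$d)
  out <- list(est = r$est, li = r$li, ui = r$ui)
  if (is.na(r$est)) out$reason <- "degenerate margin: PRR undefined"
  out
}

#' Chi-squared statistic of the fourfold table
#'
#' Yates-corrected form (default, the MHRA convention here)
#' `chi2 = n (max(0, |ad - bc| - n/2))^2 / [(a+b)(c+d)(a+c)(b+d)]` — the
#' numerator is clamped at zero so exact independence scores 0 — or the
#' uncorrected Pearson form `chi2 = n (ad - bc)^2 / [same denominator]`.
#'
#' @inheritParams ror_stats
#' @param corrected logical; `TRUE` for the Yates continuity correction.
#' @return the statistic, or `NA` when a margin is zero.
#' @export
chi2_stat <- function(tab, corrected = TRUE) {
  stopifnot(inherits(tab, "contingency_table"))
  .chi2_core(tab$a, tab$b, tab$c, tab$d, corrected)
}

#' BCPNN information component (closed-form shrinkage estimate)
#'
#' `E(IC) = log2[(a+1)(n+2)^2 / ((n+4)(a+b+1)(a+c+1))]` (bits), with
#' `V(IC) = (ln 2)^-2 [ (n-a+3)/((a+1)(n+5)) + (n-(a+b)+1)/((a+b+1)(n+3)) +
#' (n-(a+c)+1)/((a+c+1)(n+3)) ]` (bits^2) and `CI = E(IC) +/- 2 sqrt(V(IC))`.
#' The `+1` pseudo-counts shrink empty cells, so `a = 0` tables are finite.
#' `variant = "plain"` selects the alternative reading
#' `log2[(a+1)(n+2)/((a+b+1)(a+c+1))]`; both are ~0 under independence.
#'
#' @inheritParams ror_stats
#' @param variant `"n4"` (default) or `"plain"`.
#' @return list `eic, vic, li, ui`.
#' @export
bcpnn_stats <- function(tab, variant = c("n4", "plain")) {
  stopifnot(inherits(tab, "contingency_table"))
  if (tab$n <= 0) stop_srs("BCPNN requires n > 0", class = "srs_table")
  r <- .bcpnn_core(tab$a, tab$b, tab$c, tab$d, variant)
  list(eic = r$eic, vic = r$vic, li = r$li, ui = r$ui)
}

.flags_core <- function(a, prr, ror_li, prr_li, chi2, ic_li) {
  f <- function(x, thr) !is.na(x) & x > thr
  flag_ror <- a >= 3 & f(ror_li, 1)
  flag_prr <- a >= 3 & f(prr_li, 1)
  flag_mhra <- a >= 3 & !is.na(prr) & prr >= 2 & !is.na(chi2) & chi2 >= 4
  flag_bcpnn <- f(ic_li, 0)
  list(flag_ror = flag_ror, flag_prr = flag_prr, flag_mhra = flag_mhra,
       flag_bcpnn = flag_bcpnn,
       flag_consensus = flag_ror & flag_prr & flag_mhra & flag_bcpnn)
}

#' Evaluate the four signal criteria and the consensus flag
#'
#' ROR and PRR signal when `a >= 3` and the CI lower limit exceeds 1; MHRA
#' when `a >= 3`, `PRR >= 2` and `chi2 >= 4` (the configured chi-squared
#' variant); BCPNN when the IC lower limit exceeds 0. Consensus = all four.
#' Non-computable statistics make the corresponding flag `FALSE`.
#'
#' @param result one row of [mine_signals()] output, or any list/row with
#'   fields `a, prr, ror_li95, prr_li95, chi2, ic_li95`.
#' @return named logical list with the four method flags and `flag_consensus`.
#' @export
evaluate_criteria <- function(result) {
  lapply(.flags_core(result$a, result$prr, result$ror_li95, result$prr_li95,
                     result$chi2, result$ic_li95), as.logical)
}

#' Mine all drug-event pairs for disproportionality signals
#'
#' Enumerates every (drug, PT) pair observed at least once (`a >= 1`; the
#' `a >= 3` rule applies at flag time, not enumeration time), builds all
#' fourfold tables, computes ROR, PRR, chi-squared, and the BCPNN IC with
#' their 95% intervals, and evaluates the four criteria plus consensus.
#'
#' @param combos combinations from [expand_combinations()].
#' @param chi2 `"yates"` (default) or `"pearson"` — the variant the MHRA
#'   criterion uses.
#' @param ic_variant BCPNN E(IC) variant, see [bcpnn_stats()].
#' @return data.frame, one row per pair: `generic_drug, pt, a, b, c, d, n`,
#'   `ror, ror_li95, ror_ui95, prr, prr_li95, prr_ui95, chi2, eic, vic,
#'   ic_li95, ic_ui95`, and the five flags.
#' @export
mine_signals <- function(combos, chi2 = c("yates", "pearson"),
                         ic_variant = c("n4", "plain")) {
  chi2 <- match.arg(chi2); ic_variant <- match.arg(ic_variant)
  dt <- data.table(generic_drug = combos$generic_drug, pt = combos$pt)
  n <- nrow(dt)
  if (n == 0) {
    return(data.frame(generic_drug = character(), pt = character()))
  }
  pairs <- dt[, .(a = .N), by = c("generic_drug", "pt")]
  drug_m <- dt[, .(drug_total = .N), by = "generic_drug"]
  pt_m <- dt[, .(pt_total = .N), by = "pt"]
  pairs <- merge(pairs, drug_m, by = "generic_drug")
  pairs <- merge(pairs, pt_m, by = "pt")
  a <- pairs$a
  b <- pairs$drug_total - a
  c <- pairs$pt_total - a
  d <- n - a - b - c
  ror <- .ror_core(a, b, c, d)
  prr <- .prr_core(a, b, c, d)
  x2 <- .chi2_core(a, b, c, d, corrected = (chi2 == "yates"))
  ic <- .bcpnn_core(a, b, c, d, ic_variant)
  fl <- .flags_core(a, prr$est, ror$li, prr$li, x2, ic$li)
  out <- data.frame(generic_drug = pairs$generic_drug, pt = pairs$pt,
                    a = a, b = b, c = c, d = d, n = n,
                    ror = ror$est, ror_li95 = ror$li, ror_ui95 = ror$ui,
                    prr = prr$est, prr_li95 = prr$li, prr_ui95 = prr$ui,
                    chi2 = x2, eic = ic$eic, vic = ic$vic,
                    ic_li95 = ic$li, ic_ui95 = ic$ui)
  out <- cbind(out, as.data.frame(fl))
  out <- out[order(out$generic_drug, out$pt), ]
  rownames(out) <- NULL
  attr(out, "chi2_variant") <- chi2
  attr(out, "ic_variant") <- ic_variant
  out
}

#' Rank consensus-positive signals by PRR
#'
#' Signal strength is conventionally reported in PRR order. Ties are broken
#' deterministically by `a` descending, then drug name, then PT name.
#'
#' @param signals output of [mine_signals()].
#' @param top optional number of rows to keep.
#' @return the consensus-positive subset, ordered.
#' @export
rank_signals <- function(signals, top = NULL) {
  pos <- signals[!is.na(signals$flag_consensus) & signals$flag_consensus, ,
                 drop = FALSE]
  o <- order(-pos$prr, -pos$a, pos$generic_drug, pos$pt)
  pos <- pos[o, , drop = FALSE]
  rownames(pos) <- NULL
  if (!is.null(top)) pos <- head(pos, top)
  pos
}
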
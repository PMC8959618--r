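#' Search for integer fourfold tables consistent with printed signal statistics
#'
#' Published signal tables print a handful of rounded statistics (ROR lower
#' limit, PRR and its lower limit, chi-squared, IC lower limit) but not the
#' underlying cell counts. This diagnostic enumerates integer tables at a
#' fixed total `n` whose statistics round to the printed values — a
#' consistency probe, not a reconstruction: several tables can match, or
#' none, so results carry no evidential weight beyond plausibility.
#'
#' @param n total combination count of the dataset.
#' @param prr printed PRR (2 dp).
#' @param ror_li,prr_li,chi2,ic_li optional further printed statistics (2 dp);
#'   each supplied value tightens the filter.
#' @param a_range,margin_max search bounds: `a` values tried, and the maximum
#'   drug/PT margin enumerated.
#' @param chi2_corrected whether the printed chi-squared is Yates-corrected.
#' @param tol half-width of the rounding window (default 0.005, i.e. exact
#'   2-dp agreement).
#' @return data.frame of candidate tables (possibly empty) with their exact
#'   statistics.
#' @export
probe_consistent_tables <- function(n, prr, ror_li = NULL, prr_li = NULL,
                                    chi2 = NULL, ic_li = NULL,
                                    a_range = 3:60, margin_max = 1200L,
                                    chi2_corrected = TRUE, tol = 0.005) {
  out <- list()
  for (a in a_range) {
    m1 <- seq(a, min(margin_max, n - 1L))           # drug margin a+b
    # PRR ~ [a/m1]/[c/(n-m1)]; use printed PRR to bound the PT margin cheaply
    grid <- data.table::CJ(m1 = m1, m2 = seq(a, margin_max))
    aa <- a; b <- grid$m1 - aa; c <- grid$m2 - aa; d <- n - aa - b - c
    ok <- d >= 0 & b >= 0 & c > 0
    grid <- grid[ok]; b <- b[ok]; c <- c[ok]; d <- d[ok]
    if (!nrow(grid)) next
    prr_v <- (aa / (aa + b)) / (c / (c + d))
    keep <- abs(prr_v - prr) <= tol + 1e-12
    if (!is.null(prr_li) || !is.null(ror_li) || !is.null(ic_li) ||
        !is.null(chi2)) {
      b2 <- b[keep]; c2 <- c[keep]; d2 <- d[keep]
      if (!length(b2)) next
      av <- rep(aa, length(b2))
      if (!is.null(prr_li)) {
        pv <- .prr_core(av, b2, c2, d2)
        keep2 <- abs(pv$li - prr_li) <= tol + 1e-12
      } else keep2 <- rep(TRUE, length(b2))
      if (!is.null(ror_li)) {
        rv <- .ror_core(av, b2, c2, d2)
        keep2 <- keep2 & !is.na(rv$li) & abs(rv$li - ror_li) <= tol + 1e-12
      }
      if (!is.null(chi2)) {
        xv <- .chi2_core(av, b2, c2, d2, chi2_corrected)
        keep2 <- keep2 & abs(xv - chi2) <= tol + 1e-12
      }
      if (!is.null(ic_li)) {
        iv <- .bcpnn_core(av, b2, c2, d2)
        keep2 <- keep2 & abs(iv$li - ic_li) <= tol + 1e-12
      }
      b2 <- b2[keep2]; c2 <- c2[keep2]; d2 <- d2[keep2]
      if (length(b2))
        out[[length(out) + 1]] <- data.frame(a = aa, b = b2, c = c2, d = d2)
    } else if (any(keep)) {
      out[[length(out) + 1]] <- data.frame(a = aa, b = b[keep], c = c[keep],
                                           d = d[keep])
    }
  }
  if (!length(out))
    return(data.frame(a = integer(), b = integer(), c = integer(),
                      d = integer()))
  res <- do.call(rbind, out)
  rr <- .ror_core(res$a, res$b, res$c, res$d)
  pv <- .prr_core(res$a, res$b, res$c, res$d)
  res$ror_li95 <- rr$li; res$prr <- pv$est; res$prr_li95 <- pv$li
  res$chi2 <- .chi2_core(res$a, res$b, res$c, res$d, chi2_corrected)
  res$ic_li95 <- .bcpnn_core(res$a, res$b, res$c, res$d)$li
  res
}
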
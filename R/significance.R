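#' Benjamini-Hochberg step-up procedure
#'
#' Classic FDR-controlling step-up: with sorted p-values p(1) <= ... <=
#' p(m), find the largest k with p(k) <= k*q/m and reject every test whose
#' p-value is at most p(k).  The comparison is inclusive, so a single test
#' with p exactly q/m is rejected.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param q target false discovery rate in (0, 1).
#' @return Logical rejection mask aligned with `p`.
#' @examples
#' bh_stepup(c(0.01, 0.02, 0.04, 0.8), q = 0.1) # first three rejected
#' @export
bh_stepup <- function(p, q = 0.1) {
  check_pvalues(p, q)
  m <- length(p)
  ps <- sort(p)
  ok <- ps <= seq_len(m) * q / m
  if (!any(ok)) {
    return(rep(FALSE, m))
  }
  p[] <= ps[max(which(ok))]
}

#' Gavrilov-Benjamini-Sarkar adaptive step-down procedure
#'
#' Adaptive FDR step-down with critical values
#' `c_i = i*q / (m + 1 - i*(1 - q))`: walking up the sorted p-values, stop
#' before the first i with p(i) > c_i, and reject the k* smallest where k*
#' is the largest k such that p(i) <= c_i for all i <= k.  Ties are
#' resolved by rejecting every test with p <= p(k*).
#'
#' @inheritParams bh_stepup
#' @return Logical rejection mask aligned with `p`.
#' @export
gbs_stepdown <- function(p, q) {
  check_pvalues(p, q)
  m <- length(p)
  i <- seq_len(m)
  crit <- i * q / (m + 1 - i * (1 - q))
  ps <- sort(p)
  pass <- ps <= crit
  k_star <- if (pass[1L]) {
    first_fail <- which(!pass)
    if (length(first_fail)) first_fail[1L] - 1L else m
  } else {
    0L
  }
  if (k_star == 0L) {
    return(rep(FALSE, m))
  }
  p[] <= ps[k_star]
}

check_pvalues <- function(p, q) {
  if (length(p) == 0L) stop_data("empty p-value vector")
  if (anyNA(p) || any(p <= 0 | p > 1)) stop_data("p-values must lie in (0, 1]")
  if (length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop_data("q must be a single value in (0, 1)")
  }
  invisible(TRUE)
}

#' Simes combined p-value
#'
#' `min_i m * p(i) / i` over the sorted p-values: a valid family-level
#' p-value under the same conditions as the BH procedure, used here to
#' screen phenotype families in the hierarchical filter.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return A single p-value.
#' @export
simes_pvalue <- function(p) {
  if (length(p) == 0L) stop_data("empty p-value vector")
  ps <- sort(p)
  min(1, min(length(p) * ps / seq_along(ps)))
}

#' Hierarchical FDR selection of significant associations
#'
#' Selects significant SNP-phenotype associations from raw p-values,
#' treating each phenotype as a family of tests.  The default
#' (`mode = "hierarchical"`) is a two-stage screen: stage 1 combines each
#' family's p-values with [simes_pvalue()] and applies [bh_stepup()] at
#' `q1` across families; stage 2 applies [gbs_stepdown()] at `q2` within
#' each selected family.  Two alternative modes support reproduction
#' studies: `"flat"` pools all tests into one [gbs_stepdown()] at `q2`,
#' and `"fixed"` thresholds every p-value at `alpha`.
#'
#' @param records association records with at least `phenotype_id` and
#'   `p_value` columns (see [read_associations()]).
#' @param q1 stage-1 (across-family) BH level; default 0.1.
#' @param q2 stage-2 (within-family) GBS level; default 7.9e-6.
#' @param mode `"hierarchical"` (default), `"flat"` or `"fixed"`.
#' @param alpha fixed p-value threshold, required for `mode = "fixed"`.
#' @return `records` with two added columns: `family_selected` (stage-1
#'   verdict for the record's phenotype; `TRUE` everywhere in flat/fixed
#'   modes) and `significant`.  Parameters are attached as attributes
#'   `q1`, `q2`, `mode`.
#' @export
hierarchical_filter <- function(records, q1 = 0.1, q2 = 7.9e-6,
                                mode = c("hierarchical", "flat", "fixed"),
                                alpha = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records),
            all(c("phenotype_id", "p_value") %in% names(records)))
  if (nrow(records) == 0L) stop_data("no association records supplied")
  check_pvalues(records$p_value, if (mode == "fixed") 0.5 else q2)
  sig <- rep(FALSE, nrow(records))
  fam_sel <- rep(TRUE, nrow(records))
  if (mode == "fixed") {
    if (is.null(alpha)) stop_data("mode = 'fixed' requires alpha")
    sig <- records$p_value <= alpha
  } else if (mode == "flat") {
    sig <- gbs_stepdown(records$p_value, q2)
  } else {
    if (is.null(q2)) stop_data("mode = 'hierarchical' requires q2")
    fam <- split(seq_len(nrow(records)), records$phenotype_id)
    fam_p <- vapply(fam, function(ix) simes_pvalue(records$p_value[ix]), numeric(1))
    selected <- bh_stepup(fam_p, q1)
    names(selected) <- names(fam)
    fam_sel <- selected[records$phenotype_id]
    for (f in names(fam)[selected]) {
      ix <- fam[[f]]
      sig[ix] <- gbs_stepdown(records$p_value[ix], q2)
    }
  }
  records$family_selected <- unname(fam_sel)
  records$significant <- sig
  attr(records, "q1") <- q1
  attr(records, "q2") <- q2
  attr(records, "mode") <- mode
  records
}
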
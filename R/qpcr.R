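#' 2^-ddCt relative quantification
#'
#' Normalizes each sample's target Ct by the arithmetic mean of the
#' reference-target Cts (equivalent to geometric-mean normalization on the
#' expression scale), averages technical PCR replicates within a sample,
#' forms ddCt = mean dCt(treated) - mean dCt(control), and reports
#' `fc = 2^-ddCt` with a two-sided two-sample Student t-test on the
#' per-sample dCt values.
#'
#' @param qpcr a list as returned by [simulate_qpcr()] (elements `ct`,
#'   `reference_targets`, `design`), or pass the pieces separately
#' @param target target id to quantify
#' @return list: `fc`, `ddct`, `p`, `dct` (per-sample dCt with condition)
#' @export
ddct_fold_change <- function(qpcr, target) {
  ct <- qpcr$ct; refs <- qpcr$reference_targets; design <- qpcr$design
  if (!target %in% ct$target_id) stop("target '", target, "' not measured")
  if (!all(refs %in% ct$target_id)) stop("reference target(s) missing from Ct table")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) stop("Ct values must be finite and > 0")
  if (anyDuplicated(ct[, c("target_id", "sample_id", "replicate")]))
    stop("(target, sample, replicate) not unique")

  # per (sample, replicate) reference mean, then dCt, then per-sample mean
  samples <- unique(ct$sample_id[ct$target_id == target])
  dct <- vapply(samples, function(s) {
    tt <- ct[ct$target_id == target & ct$sample_id == s, ]
    d <- vapply(tt$replicate, function(r) {
      rr <- ct[ct$target_id %in% refs & ct$sample_id == s & ct$replicate == r, ]
      if (nrow(rr) != length(refs))
        stop("missing reference measurement for sample ", s, " replicate ", r)
      tt$ct[tt$replicate == r] - mean(rr$ct)
    }, 0)
    mean(d)
  }, 0)
  cond <- design$condition[match(samples, design$sample_id)]
  if (anyNA(cond)) stop("sample(s) missing from design")
  if (sum(cond == "treated") < 2 || sum(cond == "control") < 2)
    stop("need >= 2 biological replicates per condition")
  ddct <- mean(dct[cond == "treated"]) - mean(dct[cond == "control"])
  v <- stats::var(dct[cond == "treated"]) + stats::var(dct[cond == "control"])
  p <- if (v == 0) {
    if (ddct == 0) 1 else NA_real_   # degenerate noiseless plate
  } else {
    stats::t.test(dct[cond == "treated"], dct[cond == "control"],
                  var.equal = TRUE)$p.value
  }
  list(fc = 2^(-ddct), ddct = ddct, p = p,
       dct = data.frame(sample_id = samples, condition = cond, dct = unname(dct),
                        stringsAsFactors = FALSE))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Constant input is
#' undefined and signalled distinctly.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return rho in [-1, 1]
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Count validated anti-correlated pairs
#'
#' Applies the validation rule rho <= threshold to a vector of Spearman
#' correlations of miRNA-mRNA fold-change series.
#'
#' @param rho numeric vector of correlations in [-1, 1]
#' @param threshold validation cutoff (default -0.5, inclusive)
#' @return integer count of pairs with rho <= threshold
#' @export
count_validated_pairs <- function(rho, threshold = -0.5) {
  if (length(rho) && (any(rho < -1 - 1e-12) || any(rho > 1 + 1e-12)))
    stop("rho values must lie in [-1, 1]")
  sum(rho <= threshold)
}
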
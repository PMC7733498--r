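#' Pairwise disagreement flags for two design estimates
#'
#' Compares two effect estimates of the same response obtained by different
#' designs. Five binary criteria are computed: disjoint 95% confidence
#' intervals; a >100% difference in point-estimate magnitude (relative to
#' the smaller estimate); a difference in statistical significance (exactly
#' one p < 0.05); a difference in sign of the point estimates; and a
#' significantly different sign (confidence intervals strictly on opposite
#' sides of zero).
#'
#' When the smaller point estimate is exactly zero the magnitude ratio is
#' undefined; the >100% flag is then TRUE if the other estimate is nonzero
#' (the monotone limit) and FALSE if both are zero. A zero point estimate
#' counts as positive for the sign comparison.
#'
#' @param e1,e2 one-row data frames (or lists) with `point`, `ci_low`,
#'   `ci_high` and `p_value` — e.g. rows of [estimate_all()] output.
#' @param alpha significance threshold (default 0.05).
#'
#' @return A one-row data frame with logical columns `no_ci_overlap`,
#'   `gt100_magnitude`, `diff_significance`, `diff_sign`,
#'   `signif_diff_sign`.
#' @export
compare_pair <- function(e1, e2, alpha = 0.05) {
  p1 <- e1$point; p2 <- e2$point
  if (!is.finite(p1) || !is.finite(p2))
    db_stop("NonFiniteInput", "both point estimates must be finite")
  no_overlap <- e1$ci_high < e2$ci_low || e2$ci_high < e1$ci_low
  lo <- min(abs(p1), abs(p2))
  gt100 <- if (lo == 0) (max(abs(p1), abs(p2)) > 0) else abs(p1 - p2) / lo > 1
  sig1 <- e1$p_value < alpha
  sig2 <- e2$p_value < alpha
  sgn <- function(x) if (x >= 0) 1 else -1  # zero counted as positive
  diff_sign <- sgn(p1) != sgn(p2)
  signif_diff_sign <- (e1$ci_low > 0 && e2$ci_high < 0) ||
                      (e2$ci_low > 0 && e1$ci_high < 0)
  data.frame(no_ci_overlap = no_overlap, gt100_magnitude = gt100,
             diff_significance = xor(sig1, sig2), diff_sign = diff_sign,
             signif_diff_sign = signif_diff_sign)
}

design_pairs <- function() {
  labs <- estimator_labels()
  idx <- utils::combn(4L, 2L)
  data.frame(design_1 = labs[idx[1L, ]], design_2 = labs[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise disagreement table across all responses
#'
#' For each of the six pairs of design estimators, computes the proportion
#' of responses on which the two designs disagree under each criterion of
#' [compare_pair()]. Pairs in which either member failed to converge are
#' dropped from that pair's denominator.
#'
#' @param m an `estimate_matrix` from [estimate_all()], typically one arm.
#' @param alpha significance threshold.
#'
#' @return A data frame of class `pairwise_table`: one row per (arm, pair)
#'   with the five disagreement proportions and the denominator `n`.
#' @export
pairwise_table <- function(m, alpha = 0.05) {
  stopifnot(is.data.frame(m))
  flags <- c("no_ci_overlap", "gt100_magnitude", "diff_significance",
             "diff_sign", "signif_diff_sign")
  out <- do.call(rbind, lapply(split(m, m$arm), function(ma) {
    pairs <- design_pairs()
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      a <- ma[ma$estimator == pairs$design_1[k], , drop = FALSE]
      b <- ma[ma$estimator == pairs$design_2[k], , drop = FALSE]
      ids <- intersect(a$response_id[a$converged & is.finite(a$point)],
                       b$response_id[b$converged & is.finite(b$point)])
      res <- data.frame(arm = ma$arm[1L], pairs[k, , drop = FALSE],
                        stringsAsFactors = FALSE)
      if (length(ids) == 0L) {
        res[flags] <- NA_real_
        res$n <- 0L
        return(res)
      }
      fl <- do.call(rbind, lapply(ids, function(id)
        compare_pair(a[a$response_id == id, ][1L, ],
                     b[b$response_id == id, ][1L, ], alpha = alpha)))
      res[flags] <- colMeans(fl)
      res$n <- length(ids)
      res
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("pairwise_table", "data.frame")
  out
}

#' @export
print.pairwise_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L)) & names(y) != "n"
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' t-statistic agreement grid between design estimators
#'
#' Classifies every response, for each pair of designs, by the sign and
#' significance of the two t-statistics (t = point/se, significance at
#' |t| > 1.96): `same_sign_same_sig` (agreement), `same_sign_diff_sig`
#' (exactly one estimate significant), and `diff_sign_and_sig`. By default
#' the last category requires both estimates significant with opposite
#' signs; set `red = "sign_and_significance"` for the alternative reading
#' (opposite signs and a difference in significance). The first category
#' collects the remainder, so counts always sum to the number of compared
#' responses.
#'
#' @param m an `estimate_matrix` from [estimate_all()].
#' @param red rule for the strongest-disagreement category.
#'
#' @return Data frame with one row per (arm, pair): counts
#'   `same_sign_same_sig`, `same_sign_diff_sig`, `diff_sign_and_sig` and
#'   total `n`.
#' @export
t_grid <- function(m, red = c("both_significant", "sign_and_significance")) {
  red <- match.arg(red)
  stopifnot(is.data.frame(m))
  out <- do.call(rbind, lapply(split(m, m$arm), function(ma) {
    pairs <- design_pairs()
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      a <- ma[ma$estimator == pairs$design_1[k], , drop = FALSE]
      b <- ma[ma$estimator == pairs$design_2[k], , drop = FALSE]
      ids <- intersect(a$response_id[a$converged & is.finite(a$se) & a$se > 0],
                       b$response_id[b$converged & is.finite(b$se) & b$se > 0])
      t1 <- a$point[match(ids, a$response_id)] / a$se[match(ids, a$response_id)]
      t2 <- b$point[match(ids, b$response_id)] / b$se[match(ids, b$response_id)]
      s1 <- abs(t1) > 1.96; s2 <- abs(t2) > 1.96
      same_sign <- (t1 >= 0) == (t2 >= 0)
      is_red <- if (red == "both_significant") s1 & s2 & !same_sign
                else !same_sign & xor(s1, s2)
      is_orange <- !is_red & xor(s1, s2)
      data.frame(arm = ma$arm[1L], pairs[k, , drop = FALSE],
                 same_sign_same_sig = sum(!is_red & !is_orange),
                 same_sign_diff_sig = sum(is_orange),
                 diff_sign_and_sig = sum(is_red), n = length(ids),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
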
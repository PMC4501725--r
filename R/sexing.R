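#' Relative template dose from qPCR cycle thresholds
#'
#' Delta-delta-Ct quantification with explicit efficiency:
#' `ratio = (1 + efficiency) ^ ((ct_reference - ct_target) - calibrator_dct)`,
#' where `calibrator_dct` is `ct_reference - ct_target` measured on a
#' known-male (ZZ) calibrator.  Relative to that calibrator, ZZ individuals
#' give a dose near 1 for Z-linked genes and WZ individuals near 0.5 (one
#' missing Z copy = one extra cycle at perfect efficiency).
#'
#' @param ct_target Ct of the Z-linked gene (cycles); vectorised.
#' @param ct_reference Ct of the autosomal normalizer.
#' @param efficiency Amplification efficiency in `(0, 1]`.
#' @param calibrator_dct `ct_reference - ct_target` of the ZZ calibrator.
#' @return Dose ratio(s) `> 0`.
#' @examples
#' relative_dose(20, 19)            # one cycle late -> 0.5
#' relative_dose(19, 19)            # calibrator-like -> 1
#' @export
relative_dose <- function(ct_target, ct_reference, efficiency = 1,
                          calibrator_dct = 0) {
  abort_if(!is.numeric(efficiency) || efficiency <= 0 || efficiency > 1,
           "efficiency must lie in (0, 1]", class = "invalid_input")
  (1 + efficiency)^((ct_reference - ct_target) - calibrator_dct)
}

#' Estimate the male-calibrator delta-Ct from control individuals
#'
#' @param ct A Ct table (`individual_id`, `gene`, `replicate`, `ct`).
#' @param male_ids Ids of known ZZ individuals.
#' @param reference Normalizer gene name.
#' @return Named numeric `ct_reference - ct_target` medians for each
#'   Z-linked gene.
#' @export
estimate_calibrator <- function(ct, male_ids, reference = "EF1a") {
  abort_if(length(male_ids) == 0, "need at least one male control",
           class = "insufficient_data")
  sub <- ct[ct$individual_id %in% male_ids, , drop = FALSE]
  mean_ct <- mean_ct_by_gene(sub)
  zgenes <- setdiff(colnames(mean_ct), reference)
  vapply(zgenes, function(g)
    median(mean_ct[, reference] - mean_ct[, g], na.rm = TRUE), numeric(1))
}

# individuals x genes matrix of replicate-averaged Ct
mean_ct_by_gene <- function(ct) {
  abort_if(!all(c("individual_id", "gene", "ct") %in% names(ct)),
           "ct table needs individual_id, gene, ct", class = "invalid_input")
  abort_if(any(ct$ct <= 0), "Ct values must be positive",
           class = "invalid_input")
  tapply(ct$ct, list(ct$individual_id, ct$gene), mean)
}

#' Call the sex of one individual from Z-gene dose ratios
#'
#' Both Z-linked doses below `thresholds["low"]` (toward the single-copy WZ
#' value 0.5) call a female; both above `thresholds["high"]` (toward the
#' two-copy ZZ value 1.0) call a male; anything else - including the two
#' genes disagreeing - is `"ambiguous"` rather than silently misclassified.
#'
#' @param doses Named numeric with elements `Tpi` and `kettin`.
#' @param thresholds Named numeric `c(low = , high = )` with
#'   `0.5 < low <= high < 1`.
#' @return `"female"`, `"male"` or `"ambiguous"`.
#' @examples
#' call_sex(c(Tpi = 0.5, kettin = 0.52))
#' call_sex(c(Tpi = 1.02, kettin = 0.97))
#' @export
call_sex <- function(doses, thresholds = c(low = 0.70, high = 0.75)) {
  abort_if(!all(c("Tpi", "kettin") %in% names(doses)) ||
             any(is.na(doses[c("Tpi", "kettin")])),
           "doses for both Tpi and kettin are required",
           class = "insufficient_data")
  abort_if(any(doses[c("Tpi", "kettin")] <= 0), "doses must be positive",
           class = "invalid_input")
  lo <- thresholds[["low"]]; hi <- thresholds[["high"]]
  abort_if(!(lo > 0.5 && hi < 1 && lo <= hi),
           "need 0.5 < low <= high < 1", class = "invalid_input")
  z <- doses[c("Tpi", "kettin")]
  if (all(z < lo)) "female" else if (all(z > hi)) "male" else "ambiguous"
}

#' Molecular sexing of a qPCR cohort
#'
#' Replicate-averages Ct per individual and gene, converts the two Z-linked
#' genes to dose ratios against the autosomal normalizer with
#' [relative_dose()], and calls each individual with [call_sex()].
#'
#' @param ct Ct table (`individual_id`, `gene`, `replicate`, `ct`) containing
#'   genes `Tpi`, `kettin` and the normalizer.
#' @param efficiency Amplification efficiency.
#' @param calibrator Named numeric calibrator delta-Ct per Z gene (e.g. from
#'   [estimate_calibrator()]); defaults to 0 for both, appropriate when
#'   baseline Cts of target and normalizer coincide.
#' @param thresholds See [call_sex()].
#' @param reference Normalizer gene name.
#' @return data.frame (`individual_id`, `dose_Tpi`, `dose_kettin`, `call`).
#' @export
sex_calls <- function(ct, efficiency = 1,
                      calibrator = c(Tpi = 0, kettin = 0),
                      thresholds = c(low = 0.70, high = 0.75),
                      reference = "EF1a") {
  mean_ct <- mean_ct_by_gene(ct)
  need <- c("Tpi", "kettin", reference)
  abort_if(!all(need %in% colnames(mean_ct)),
           "missing gene(s): ",
           paste(setdiff(need, colnames(mean_ct)), collapse = ", "),
           class = "insufficient_data")
  abort_if(anyNA(mean_ct[, need]),
           "some individuals lack measurements of all three genes",
           class = "insufficient_data")
  dose_tpi <- relative_dose(mean_ct[, "Tpi"], mean_ct[, reference],
                            efficiency, calibrator[["Tpi"]])
  dose_ket <- relative_dose(mean_ct[, "kettin"], mean_ct[, reference],
                            efficiency, calibrator[["kettin"]])
  calls <- vapply(seq_len(nrow(mean_ct)), function(i)
    call_sex(c(Tpi = unname(dose_tpi[i]), kettin = unname(dose_ket[i])),
             thresholds),
    character(1))
  data.frame(individual_id = rownames(mean_ct), dose_Tpi = unname(dose_tpi),
             dose_kettin = unname(dose_ket), call = calls,
             stringsAsFactors = FALSE)
}

#' Exact binomial test for brood sex-ratio distortion
#'
#' Two-sided exact test of the observed female count against a binomial null:
#' the smaller tail probability is doubled and capped at 1.  An all-female
#' brood of 302 (and 0 males) under a balanced null gives `p = 2^-301`.
#'
#' @param n_female,n_male Non-negative counts, not both zero.
#' @param p Null female proportion.
#' @return List of class `brood_test`: `n_female`, `n_male`, `p_null`,
#'   `p_value`.
#' @examples
#' brood_test(10, 0)$p_value  # 2^-9
#' @export
brood_test <- function(n_female, n_male, p = 0.5) {
  abort_if(n_female < 0 || n_male < 0, "counts must be >= 0",
           class = "invalid_input")
  abort_if(n_female + n_male == 0, "counts must not both be zero",
           class = "invalid_input")
  abort_if(p <= 0 || p >= 1, "null proportion must lie in (0, 1)",
           class = "invalid_input")
  n <- n_female + n_male
  lower <- pbinom(n_female, n, p)
  upper <- pbinom(n_female - 1, n, p, lower.tail = FALSE)
  structure(list(n_female = n_female, n_male = n_male, p_null = p,
                 p_value = min(1, 2 * min(lower, upper))),
            class = "brood_test")
}

#' @export
print.brood_test <- function(x, ...) {
  cat(sprintf(
    "<brood_test> %d female : %d male vs null %.2f; two-sided p = %.4g\n",
    x$n_female, x$n_male, x$p_null, x$p_value))
  invisible(x)
}
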
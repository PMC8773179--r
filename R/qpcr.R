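#' Relative expression by the comparative Ct method
#'
#' For every sample, computes dCt = target Ct - reference Ct, then
#' ddCt = dCt - mean(dCt of the calibrator condition for the same
#' target/reference pair), and relative abundance 2^(-ddCt).
#' Amplification efficiency is fixed at 100% (base 2); the calibrator
#' group therefore has mean log2 relative abundance 0 by construction.
#'
#' @param records data.frame with columns `sample_id`, `condition`,
#'   `target_gene`, `target_ct`, `reference_gene`, `reference_ct`
#' @param calibrator_condition condition label of the calibrator
#'   (default `"NT"`)
#' @return input data.frame with added columns `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`
#' @export
relative_expression <- function(records, calibrator_condition = "NT") {
  required <- c("sample_id", "condition", "target_gene", "target_ct",
                "reference_gene", "reference_ct")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("Ct table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- records
  out$delta_ct <- out$target_ct - out$reference_ct
  out$delta_delta_ct <- NA_real_
  for (tg in unique(out$target_gene)) {
    sel <- out$target_gene == tg
    refs <- unique(out$reference_gene[sel])
    if (length(refs) != 1L) {
      stop(sprintf("target %s measured against multiple reference genes: %s",
                   tg, paste(refs, collapse = ", ")), call. = FALSE)
    }
    cal <- sel & out$condition == calibrator_condition
    if (!any(cal)) {
      stop(sprintf("no calibrator ('%s') records for target %s",
                   calibrator_condition, tg), call. = FALSE)
    }
    out$delta_delta_ct[sel] <- out$delta_ct[sel] - mean(out$delta_ct[cal])
  }
  out$rel_expr <- 2^(-out$delta_delta_ct)
  out
}

#' Knockdown summary per condition
#'
#' Mean, SD and n of relative expression per condition and target, plus
#' percent knockdown = 100 x (1 - mean). SD is NA for single replicates.
#'
#' @param rel data.frame from [relative_expression()]
#' @return data.frame `condition`, `target_gene`, `mean_rel_expr`, `sd`,
#'   `n`, `percent_knockdown`
#' @export
knockdown_summary <- function(rel) {
  if (!"rel_expr" %in% names(rel)) {
    stop("input must come from relative_expression()", call. = FALSE)
  }
  groups <- unique(rel[, c("condition", "target_gene")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    v <- rel$rel_expr[rel$condition == groups$condition[i] &
                        rel$target_gene == groups$target_gene[i]]
    data.frame(condition = groups$condition[i],
               target_gene = groups$target_gene[i],
               mean_rel_expr = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               n = length(v),
               percent_knockdown = 100 * (1 - mean(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
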
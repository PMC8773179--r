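#' Summarize a replicate group
#'
#' Mean, sample standard deviation (n - 1 denominator) and size of one
#' group of well measurements.
#'
#' @param values numeric vector, at least one value
#' @return list of class `group_stats` with `mean`, `sd` (NA when n < 2)
#'   and `n`
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to summarize", call. = FALSE)
  structure(list(mean = mean(values),
                 sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
                 n = length(values)),
            class = "group_stats")
}

#' Strictly standardized mean difference
#'
#' The SSMD effect size between two replicate groups,
#' \deqn{\beta = (\bar X_1 - \bar X_2) / \sqrt{s_1^2 + s_2^2},}
#' the plain method-of-moments form with sample standard deviations.
#' It is antisymmetric in its arguments and invariant to a common
#' positive scaling or additive shift of both groups, which is why
#' scoring against the on-plate reference cancels plate effects.
#'
#' When both SDs are zero the statistic degenerates: identical means
#' give 0, different means give signed infinity (flag this via
#' [score_plate()]'s `degenerate_variance`).
#'
#' @param g1,g2 `group_stats` (or lists with `mean`, `sd`, `n`); both
#'   need n >= 2
#' @return numeric beta, possibly +/-Inf in the degenerate case
#' @export
ssmd <- function(g1, g2) {
  if (g1$n < 2L || g2$n < 2L) {
    stop("ssmd requires n >= 2 in both groups", call. = FALSE)
  }
  denom <- sqrt(g1$sd^2 + g2$sd^2)
  diff <- g1$mean - g2$mean
  if (denom == 0) {
    if (diff == 0) return(0)
    return(sign(diff) * Inf)
  }
  diff / denom
}

#' Score one condition plate against its non-targeting wells
#'
#' Computes, for every candidate and control gene on the plate, the SSMD
#' beta of its replicate wells versus all NT wells on the same physical
#' plate, for the requested readout. Genes with fewer than two usable
#' wells are flagged (`insufficient_replicates`) and given no beta;
#' degenerate zero-variance comparisons are flagged
#' (`degenerate_variance`) and return signed infinity.
#'
#' @param measurements `screen_measurements` rows for one condition plate
#' @param design `plate_design` providing the well-to-gene layout
#' @param readout `"secretion"` (signal column) or `"cell_count"`
#' @return data.frame: `gene`, `role`, `condition`, `set_id`, `beta`,
#'   `mean_candidate`, `sd_candidate`, `n_candidate`, `mean_nt`,
#'   `sd_nt`, `n_nt`, `flags`
#' @export
score_plate <- function(measurements, design,
                        readout = c("secretion", "cell_count")) {
  readout <- match.arg(readout)
  plate <- unique(measurements$plate)
  if (length(plate) != 1L) {
    stop("score_plate expects measurements from exactly one plate",
         call. = FALSE)
  }
  set_id <- unique(measurements$set_id)
  condition <- unique(measurements$condition)
  value_col <- if (readout == "secretion") "signal" else "cell_count"

  lay <- design$layout[design$layout$set_id == set_id &
                         design$layout$role != "empty", , drop = FALSE]
  m <- match(measurements$well, lay$well)
  gene <- lay$gene_symbol[m]
  role <- lay$role[m]
  values <- as.numeric(measurements[[value_col]])
  usable <- !is.na(values) & is.finite(values) & !is.na(gene)

  nt_values <- values[usable & role == "nt"]
  if (length(nt_values) < 2L) {
    stop(sprintf("plate %s has fewer than 2 usable NT wells; unscoreable",
                 plate), call. = FALSE)
  }
  nt <- summarize_group(nt_values)

  scored_roles <- role %in% c("candidate", "control")
  genes <- unique(data.frame(gene = gene[scored_roles],
                             role = role[scored_roles],
                             stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene[i]
    v <- values[usable & !is.na(gene) & gene == g & scored_roles]
    flags <- character()
    if (length(v) < 2L) {
      beta <- NA_real_
      gs <- if (length(v)) summarize_group(v) else
        list(mean = NA_real_, sd = NA_real_, n = 0L)
      flags <- c(flags, "insufficient_replicates")
    } else {
      gs <- summarize_group(v)
      beta <- ssmd(gs, nt)
      if (is.infinite(beta)) flags <- c(flags, "degenerate_variance")
    }
    data.frame(gene = g, role = genes$role[i], condition = condition,
               set_id = set_id, beta = beta,
               mean_candidate = gs$mean, sd_candidate = gs$sd,
               n_candidate = gs$n,
               mean_nt = nt$mean, sd_nt = nt$sd, n_nt = nt$n,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score a whole screen for secretion and cell number
#'
#' Runs [score_plate()] on every condition plate for both readouts and
#' merges them into one score table per gene x condition x set.
#'
#' @param measurements `screen_measurements` for the full screen
#' @param design `plate_design`
#' @return data.frame of class `screen_scores`: per gene/condition/set,
#'   `beta_secretion` and `beta_cellnumber` with the underlying group
#'   statistics of the secretion readout and combined flags
#' @export
score_screen <- function(measurements, design) {
  cp <- design$condition_plates
  per_plate <- lapply(seq_len(nrow(cp)), function(i) {
    mp <- measurements[measurements$plate == cp$plate[i], , drop = FALSE]
    sec <- score_plate(mp, design, "secretion")
    cells <- score_plate(mp, design, "cell_count")
    k <- match(paste(sec$gene, sec$condition), paste(cells$gene, cells$condition))
    sec$beta_cellnumber <- cells$beta[k]
    cell_flags <- cells$flags[k]
    sec$flags <- ifelse(nchar(sec$flags) & nchar(cell_flags),
                        paste(sec$flags, cell_flags, sep = ";"),
                        paste0(sec$flags, cell_flags))
    names(sec)[names(sec) == "beta"] <- "beta_secretion"
    sec
  })
  out <- do.call(rbind, per_plate)
  out <- out[, c("gene", "role", "condition", "set_id",
                 "beta_secretion", "beta_cellnumber",
                 "mean_candidate", "sd_candidate", "n_candidate",
                 "mean_nt", "sd_nt", "n_nt", "flags")]
  rownames(out) <- NULL
  class(out) <- c("screen_scores", "data.frame")
  out
}

#' Call hits from SSMD scores
#'
#' Per condition, a gene is an up hit if its secretion beta is at or
#' above `up_cut` and a down hit if at or below `down_cut` -- unless its
#' cell-number beta also falls at or below `viability_cut`, in which
#' case the secretion decrease is attributed to cell loss and the gene
#' is excluded (viability filter; it never touches up hits). A gene is a
#' hit overall if it is up or down in at least one condition.
#'
#' @param scores `screen_scores` from [score_screen()]
#' @param up_cut inclusive upper beta cut-off (default +1.5)
#' @param down_cut inclusive lower beta cut-off (default -1.5)
#' @param viability_cut inclusive cell-number beta cut-off below which a
#'   down candidate is excluded (default -1.5)
#' @param candidates_only drop control-role genes from the calls
#'   (default TRUE)
#' @return data.frame of class `hit_calls`: one row per gene with
#'   per-condition `direction_<condition>` columns, `conditions_hit`
#'   (comma-separated labels), `viability_excluded`, and `hit`
#' @export
call_hits <- function(scores, up_cut = 1.5, down_cut = -1.5,
                      viability_cut = -1.5, candidates_only = TRUE) {
  stopifnot(up_cut > 0, down_cut < 0, viability_cut < 0)
  s <- as.data.frame(scores)
  if (candidates_only) s <- s[s$role == "candidate", , drop = FALSE]

  up <- !is.na(s$beta_secretion) & s$beta_secretion >= up_cut
  down_raw <- !is.na(s$beta_secretion) & s$beta_secretion <= down_cut
  killed <- !is.na(s$beta_cellnumber) & s$beta_cellnumber <= viability_cut
  excluded <- down_raw & killed
  down <- down_raw & !excluded
  s$direction <- ifelse(up, "up", ifelse(down, "down", "none"))
  s$excluded <- excluded

  conditions <- unique(s$condition)
  genes <- unique(s$gene)
  calls <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cond in conditions) {
    d <- s$direction[s$condition == cond][match(genes, s$gene[s$condition == cond])]
    calls[[paste0("direction_", condition_slug(cond))]] <-
      ifelse(is.na(d), "none", d)
  }
  hit_conds <- vapply(genes, function(g) {
    rows <- s[s$gene == g & s$direction != "none", , drop = FALSE]
    paste(unique(rows$condition), collapse = ",")
  }, "")
  calls$conditions_hit <- hit_conds
  calls$viability_excluded <- vapply(genes, function(g) {
    any(s$excluded[s$gene == g])
  }, NA)
  calls$hit <- nzchar(calls$conditions_hit)
  attr(calls, "conditions") <- conditions
  attr(calls, "cuts") <- c(up_cut = up_cut, down_cut = down_cut,
                           viability_cut = viability_cut)
  class(calls) <- c("hit_calls", "data.frame")
  calls
}

#' Integrate hit calls across conditions
#'
#' Builds per-direction, per-condition hit sets, all their Venn regions
#' (exclusive intersections) and union counts.
#'
#' @param calls `hit_calls` from [call_hits()]
#' @return list with `per_condition` (direction x condition counts),
#'   `venn` (per direction: named exclusive region -> count), and
#'   `union` (genes up / down / total in at least one condition)
#' @export
integrate_conditions <- function(calls) {
  conditions <- attr(calls, "conditions")
  if (is.null(conditions)) {
    dir_cols <- grep("^direction_", names(calls), value = TRUE)
    conditions <- sub("^direction_", "", dir_cols)
  }
  sets <- list(up = list(), down = list())
  for (cond in conditions) {
    col <- paste0("direction_", condition_slug(cond))
    sets$up[[cond]] <- calls$gene[calls[[col]] == "up"]
    sets$down[[cond]] <- calls$gene[calls[[col]] == "down"]
  }
  venn_regions <- function(gene_sets) {
    all_genes <- unique(unlist(gene_sets))
    if (!length(all_genes)) return(stats::setNames(integer(0), character(0)))
    membership <- vapply(all_genes, function(g) {
      paste(names(gene_sets)[vapply(gene_sets, function(s) g %in% s, NA)],
            collapse = "&")
    }, "")
    table(membership)
  }
  venn <- lapply(sets, venn_regions)
  per_condition <- expand.grid(direction = c("up", "down"),
                               condition = conditions,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
  per_condition$count <- mapply(function(d, cond) length(sets[[d]][[cond]]),
                                per_condition$direction,
                                per_condition$condition)
  union_up <- unique(unlist(sets$up))
  union_down <- unique(unlist(sets$down))
  list(per_condition = per_condition,
       venn = lapply(venn, function(v) as.list(stats::setNames(as.integer(v), names(v)))),
       union = list(up = length(union_up), down = length(union_down),
                    total = length(unique(c(union_up, union_down)))))
}

#' Fold induction of NT wells over basal
#'
#' Per plate set, the ratio of mean NT signal on each stimulated
#' condition plate to mean NT signal on the basal plate of the same set.
#' The screen's QC expectation is roughly 2--3-fold at 20 mM glucose and
#' 5--6-fold with IBMX.
#'
#' @param measurements `screen_measurements`
#' @param design `plate_design`
#' @param basal basal condition label (default `"0mM"`)
#' @return data.frame `set_id`, `condition`, `fold` (basal rows have
#'   fold 1)
#' @export
fold_induction <- function(measurements, design, basal = "0mM") {
  lay <- design$layout
  nt_wells <- lay[lay$role == "nt", c("set_id", "well")]
  key <- paste(measurements$set_id, measurements$well)
  is_nt <- key %in% paste(nt_wells$set_id, nt_wells$well)
  nt <- measurements[is_nt, , drop = FALSE]
  if (!nrow(nt)) stop("no NT wells found in measurements", call. = FALSE)

  agg <- stats::aggregate(signal ~ set_id + condition, data = nt, FUN = mean)
  out <- list()
  for (s in unique(agg$set_id)) {
    base_mean <- agg$signal[agg$set_id == s & agg$condition == basal]
    if (!length(base_mean) || base_mean <= 0) {
      stop(sprintf("set %s: basal NT mean absent or non-positive", s),
           call. = FALSE)
    }
    rows <- agg[agg$set_id == s, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      set_id = s, condition = rows$condition,
      fold = rows$signal / base_mean, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$set_id, match(res$condition, design$conditions)), ]
  rownames(res) <- NULL
  res
}

#' Default control-behavior expectations
#'
#' INSULIN and PLK1 must score beta <= -2 on every plate and condition,
#' ZMIZ1 beta <= -2 at 20 mM glucose, HNF4A beta >= 1.5 at 20 mM.
#'
#' @return data.frame `gene`, `condition` (`"all"` = every condition),
#'   `op` (`"le"`/`"ge"`), `threshold`
#' @export
default_control_expectations <- function() {
  data.frame(
    gene = c("INSULIN", "PLK1", "ZMIZ1", "HNF4A"),
    condition = c("all", "all", "20mM", "20mM"),
    op = c("le", "le", "le", "ge"),
    threshold = c(-2, -2, -2, 1.5),
    stringsAsFactors = FALSE
  )
}

#' Control QC report
#'
#' Evaluates every control gene's secretion beta on every plate set and
#' condition against the declared expectations, and reports NT fold
#' induction per set. Missing controls are reported as missing, not
#' raised as errors.
#'
#' @param scores `screen_scores`
#' @param measurements `screen_measurements` (for fold induction)
#' @param design `plate_design`
#' @param expectations data.frame as from
#'   [default_control_expectations()]
#' @param basal basal condition label
#' @return list of class `qc_report`: `controls` (per set/condition/gene
#'   beta with `pass`/`missing`), `fold_induction`, `all_pass`
#' @export
qc_controls <- function(scores, measurements, design,
                        expectations = default_control_expectations(),
                        basal = "0mM") {
  s <- as.data.frame(scores)
  rows <- list()
  for (i in seq_len(nrow(expectations))) {
    g <- expectations$gene[i]
    conds <- if (expectations$condition[i] == "all") design$conditions
             else expectations$condition[i]
    for (cond in conds) {
      for (set in sort(unique(design$condition_plates$set_id))) {
        beta <- s$beta_secretion[s$gene == g & s$condition == cond &
                                   s$set_id == set]
        missing <- length(beta) == 0L || all(is.na(beta))
        beta <- if (missing) NA_real_ else beta[1]
        pass <- if (missing) FALSE else switch(expectations$op[i],
          le = beta <= expectations$threshold[i],
          ge = beta >= expectations$threshold[i],
          stop("unknown op"))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, set_id = set, beta = beta,
          op = expectations$op[i], threshold = expectations$threshold[i],
          pass = pass, missing = missing, stringsAsFactors = FALSE)
      }
    }
  }
  controls <- do.call(rbind, rows)
  folds <- fold_induction(measurements, design, basal = basal)
  structure(list(controls = controls, fold_induction = folds,
                 all_pass = all(controls$pass)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d control checks pass\n",
              sum(x$controls$pass), nrow(x$controls)))
  invisible(x)
}
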
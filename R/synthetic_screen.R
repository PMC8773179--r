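#' Noise and signal configuration for the synthetic screen
#'
#' The generator produces per-well secreted-insulin signals (arbitrary
#' HTRF-ratio units) and cell counts with the statistical structure the
#' downstream analysis assumes: multiplicative log-normal well noise and
#' per-plate effects on signal, truncated-Gaussian counts. Condition
#' folds default to 2.5x (20 mM glucose) and 5.5x (20 mM + IBMX) over
#' basal, the middle of the 2--3-fold and 5--6-fold induction the assay
#' shows in non-targeting wells.
#'
#' @param well_cv coefficient of variation of the multiplicative
#'   log-normal well noise on signal (default 0.15)
#' @param plate_sigma SD of the log-scale per-plate effect (default 0.1);
#'   applied per condition-replica plate, which is exactly what per-plate
#'   SSMD scoring must cancel
#' @param base_signal mean NT signal at 0 mM glucose, arbitrary units
#' @param condition_fold named vector of secretion fold over basal per
#'   condition; the basal condition must map to 1
#' @param base_cells expected cells per well (default 15000, the seeding
#'   density)
#' @param cell_cv CV of the cell count around its expectation
#' @return list of class `noise_config`
#' @export
noise_config <- function(well_cv = 0.15,
                         plate_sigma = 0.1,
                         base_signal = 1000,
                         condition_fold = c("0mM" = 1, "20mM" = 2.5,
                                            "20mM+IBMX" = 5.5),
                         base_cells = 15000,
                         cell_cv = 0.1) {
  stopifnot(well_cv >= 0, plate_sigma >= 0, base_signal > 0,
            all(condition_fold > 0), base_cells > 0, cell_cv >= 0)
  if (!isTRUE(all.equal(unname(condition_fold[1]), 1))) {
    stop("the first (basal) condition fold must equal 1", call. = FALSE)
  }
  structure(list(well_cv = well_cv, plate_sigma = plate_sigma,
                 base_signal = base_signal, condition_fold = condition_fold,
                 base_cells = base_cells, cell_cv = cell_cv),
            class = "noise_config")
}

# canonical control-siRNA effects, calibrated so that under default noise
# INSULIN/PLK1 score beta <= -2 on every plate, ZMIZ1 beta <= -2 at 20 mM,
# and HNF4A beta >= 1.5 at 20 mM with high probability
control_effects <- function(conditions, nt_gene = "NT") {
  eff <- list()
  sec <- function(gene, mult_by_cond, cells) {
    data.frame(gene = gene, condition = conditions,
               secretion_multiplier = mult_by_cond,
               cellnumber_multiplier = cells, stringsAsFactors = FALSE)
  }
  m1 <- rep(1, length(conditions))
  at <- function(cond, value, default = 1) {
    ifelse(conditions %in% cond, value, default)
  }
  rbind(
    sec(nt_gene, m1, 1),
    sec("INSULIN", rep(0.2, length(conditions)), 1),
    sec("PLK1", rep(0.2, length(conditions)), 0.3),
    sec("ZMIZ1", at(c("0mM", "20mM"), 0.5, 0.7), 1),
    sec("HNF4A", at("20mM", 1.8), 1)
  )
}

#' Plant ground-truth gene effects for a synthetic screen
#'
#' Assigns secretion and cell-number multipliers per gene and condition:
#' `n_up` randomly chosen candidate genes get `up_multiplier` (> 1) in
#' every condition, `n_down` get `down_multiplier` (< 1), genes in
#' `viability_killed` get reduced cell number and secretion (the class
#' the viability filter must remove), and all others are null
#' (multiplier 1). Control siRNAs always carry their canonical effects.
#'
#' @param genes character vector of candidate gene symbols
#' @param n_up,n_down numbers of planted positive/negative secretion
#'   regulators (defaults 23 and 68, the screen's reported hit counts)
#' @param up_multiplier,down_multiplier planted secretion multipliers;
#'   defaults 2.0 and 0.3 correspond to true standardized effect sizes
#'   of about +3 and -5 under the default well CV
#' @param viability_killed genes whose knockdown kills cells
#'   (cell-number multiplier `killed_cell_multiplier`, secretion 0.5x)
#' @param conditions condition labels the effects apply to
#' @param killed_cell_multiplier cell-number multiplier for killed genes
#' @param seed integer seed for choosing which genes carry effects
#' @param nt_gene non-targeting gene symbol (always null)
#' @return data.frame of class `effect_map`: `gene`, `condition`,
#'   `secretion_multiplier`, `cellnumber_multiplier`
#' @export
plant_effects <- function(genes,
                          n_up = 23L, n_down = 68L,
                          up_multiplier = 2.0, down_multiplier = 0.3,
                          viability_killed = character(),
                          conditions = c("0mM", "20mM", "20mM+IBMX"),
                          killed_cell_multiplier = 0.3,
                          seed = 1L,
                          nt_gene = "NT") {
  stopifnot(up_multiplier > 1, down_multiplier > 0, down_multiplier < 1)
  genes <- setdiff(genes, c(nt_gene, "INSULIN", "PLK1", "ZMIZ1", "HNF4A"))
  if (!all(viability_killed %in% genes)) {
    stop("viability_killed contains genes not in `genes`", call. = FALSE)
  }
  if (n_up + n_down + length(viability_killed) > length(genes)) {
    stop("n_up + n_down + length(viability_killed) exceeds gene count",
         call. = FALSE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  pool <- setdiff(genes, viability_killed)
  picked <- sample(pool, n_up + n_down)
  up <- picked[seq_len(n_up)]
  down <- picked[n_up + seq_len(n_down)]
  if (length(intersect(up, down))) {
    stop("a gene was planted as both up and down", call. = FALSE)
  }

  sec_mult <- rep(1, length(genes))
  cell_mult <- rep(1, length(genes))
  sec_mult[genes %in% up] <- up_multiplier
  sec_mult[genes %in% down] <- down_multiplier
  sec_mult[genes %in% viability_killed] <- 0.5
  cell_mult[genes %in% viability_killed] <- killed_cell_multiplier

  cand <- data.frame(
    gene = rep(genes, each = length(conditions)),
    condition = rep(conditions, times = length(genes)),
    secretion_multiplier = rep(sec_mult, each = length(conditions)),
    cellnumber_multiplier = rep(cell_mult, each = length(conditions)),
    stringsAsFactors = FALSE
  )
  out <- rbind(control_effects(conditions, nt_gene), cand)
  rownames(out) <- NULL
  class(out) <- c("effect_map", "data.frame")
  out
}

#' Simulate per-well screen measurements
#'
#' For every condition-replica plate and non-empty well, draws
#' `signal = base_signal * condition_fold * secretion_multiplier *
#' plate_effect * eps`, with `plate_effect ~ LogNormal(0, plate_sigma^2)`
#' per plate and `eps` a unit-mean log-normal with CV `well_cv`; the cell
#' count is `round(Normal(base_cells * cellnumber_multiplier,
#' (cell_cv * base_cells)^2))` truncated at zero. A fixed seed
#' reproduces the dataset exactly.
#'
#' @param design `plate_design` from [assign_wells()]
#' @param effects `effect_map` from [plant_effects()]; genes absent from
#'   the map are treated as null; `NULL` simulates a fully null screen
#' @param noise `noise_config`
#' @param seed integer seed
#' @return data.frame of class `screen_measurements` with columns
#'   `set_id`, `condition`, `plate`, `well`, `signal`, `cell_count`
#' @export
simulate_screen <- function(design, effects = NULL,
                            noise = noise_config(), seed = 1L) {
  stopifnot(inherits(design, "plate_design"))
  missing_cond <- setdiff(design$conditions, names(noise$condition_fold))
  if (length(missing_cond)) {
    stop("no condition_fold for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  if (is.null(effects)) {
    effects <- data.frame(gene = character(), condition = character(),
                          secretion_multiplier = numeric(),
                          cellnumber_multiplier = numeric())
  }

  lay <- design$layout[design$layout$role != "empty", , drop = FALSE]
  cp <- design$condition_plates
  sdlog <- sqrt(log(1 + noise$well_cv^2))
  meanlog <- -sdlog^2 / 2  # unit-mean well noise

  out <- vector("list", nrow(cp))
  for (i in seq_len(nrow(cp))) {
    sel <- lay[lay$set_id == cp$set_id[i], , drop = FALSE]
    cond <- cp$condition[i]
    ekey <- paste(effects$gene, effects$condition)
    m <- match(paste(sel$gene_symbol, cond), ekey)
    sec_mult <- ifelse(is.na(m), 1, effects$secretion_multiplier[m])
    cell_mult <- ifelse(is.na(m), 1, effects$cellnumber_multiplier[m])

    plate_effect <- if (noise$plate_sigma > 0)
      stats::rlnorm(1, 0, noise$plate_sigma) else 1
    eps <- if (noise$well_cv > 0)
      stats::rlnorm(nrow(sel), meanlog, sdlog) else rep(1, nrow(sel))
    signal <- noise$base_signal * noise$condition_fold[[cond]] *
      sec_mult * plate_effect * eps

    mu_cells <- noise$base_cells * cell_mult
    cells <- if (noise$cell_cv > 0)
      stats::rnorm(nrow(sel), mu_cells, noise$cell_cv * noise$base_cells)
    else mu_cells
    cells <- pmax(0, round(cells))

    out[[i]] <- data.frame(set_id = cp$set_id[i], condition = cond,
                           plate = cp$plate[i], well = sel$well,
                           signal = signal, cell_count = as.integer(cells),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("screen_measurements", "data.frame")
  res
}

#' Simulate a qPCR Ct table for knockdown validation
#'
#' Inverts the delta-delta-Ct model at 100% amplification efficiency:
#' residual expression r = 1 - knockdown shifts the target Ct of the
#' knocked-down sample by -log2(r) cycles relative to the non-targeting
#' calibrator; reference-gene Ct is unaffected. Gaussian cycle noise of
#' SD `noise_sd` is added to every Ct.
#'
#' @param knockdown named numeric vector: per-gene knockdown fraction in
#'   \[0, 1)
#' @param ct_target_nt target-gene Ct in the calibrator sample (cycles)
#' @param ct_ref reference-gene Ct (cycles)
#' @param noise_sd Gaussian Ct noise SD in cycles (0 for noise-free)
#' @param n_replicates replicate samples per condition
#' @param reference_gene reference gene label
#' @param calibrator_condition label of the calibrator (NT) condition
#' @param seed integer seed
#' @return data.frame with columns `sample_id`, `condition`,
#'   `target_gene`, `target_ct`, `reference_gene`, `reference_ct`
#' @export
simulate_qpcr <- function(knockdown,
                          ct_target_nt = 22, ct_ref = 18,
                          noise_sd = 0.15, n_replicates = 3L,
                          reference_gene = "REF",
                          calibrator_condition = "NT",
                          seed = 1L) {
  if (any(knockdown < 0 | knockdown >= 1)) {
    stop("knockdown fractions must lie in [0, 1); 1 implies infinite Ct",
         call. = FALSE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  rows <- lapply(names(knockdown), function(g) {
    # each target gene is measured in the calibrator and in its own
    # knockdown condition; -log2(residual) cycles are added to target Ct
    conds <- c(calibrator_condition, paste0("si", g))
    shift <- c(0, -log2(1 - knockdown[[g]]))
    per_cond <- lapply(seq_along(conds), function(j) {
      data.frame(
        sample_id = sprintf("%s_%s_rep%d", g, conds[j], seq_len(n_replicates)),
        condition = conds[j],
        target_gene = g,
        target_ct = ct_target_nt + shift[j] +
          stats::rnorm(n_replicates, 0, noise_sd),
        reference_gene = reference_gene,
        reference_ct = ct_ref + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, per_cond)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
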
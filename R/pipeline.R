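#' Build a synthetic cherry-pick library table
#'
#' Generates a deterministic in-silico siRNA library: `n_genes`
#' candidate genes plus the NT and control siRNA entries, laid out
#' row-major across as many 384-well source plates as needed. Useful for
#' tests and demonstrations when no real library export is at hand; it
#' is synthetic and carries placeholder accessions.
#'
#' @param n_genes number of candidate genes (default 521)
#' @param nt_gene non-targeting gene symbol
#' @return `sirna_library` data.frame
#' @export
synthetic_library <- function(n_genes = 521L, nt_gene = "NT") {
  ctrl <- c(nt_gene, "INSULIN", "PLK1", "ZMIZ1", "HNF4A")
  genes <- c(ctrl, sprintf("GENE%04d", seq_len(n_genes)))
  n <- length(genes)
  plate_idx <- (seq_len(n) - 1L) %/% PLATE_WELLS + 1L
  well_idx <- (seq_len(n) - 1L) %% PLATE_WELLS + 1L
  lib <- data.frame(
    uniprot_id = c(paste0("CTRL", seq_along(ctrl)),
                   sprintf("P%05d", seq_len(n_genes))),
    gene_symbol = genes,
    catalog_id = NA_character_,
    source_plate = sprintf("SRC%02d", plate_idx),
    source_well = well_labels()[well_idx],
    stringsAsFactors = FALSE
  )
  class(lib) <- c("sirna_library", "data.frame")
  lib
}

#' Default pipeline configuration
#'
#' Every design decision of the pipeline is a field here and can be
#' overridden from a JSON config file; the full snapshot is echoed into
#' the run manifest.
#'
#' @return nested list of configuration defaults
#' @export
default_config <- function() {
  list(
    library_path = NULL,          # NULL -> synthetic_library(n_genes)
    n_genes = 521L,
    replicates = 3L,
    capacity = 75L,
    conditions = c("0mM", "20mM", "20mM+IBMX"),
    nt_n = 33L,
    control_n = c(INSULIN = 8L, PLK1 = 8L, ZMIZ1 = 8L, HNF4A = 8L),
    nt_gene = "NT",
    randomize_controls = TRUE,
    volume_nl = 100,
    zero_pad_wells = FALSE,
    noise = list(well_cv = 0.15, plate_sigma = 0.1, base_signal = 1000,
                 condition_fold = c("0mM" = 1, "20mM" = 2.5,
                                    "20mM+IBMX" = 5.5),
                 base_cells = 15000, cell_cv = 0.1),
    effects = list(n_up = 23L, n_down = 68L,
                   up_multiplier = 2.0, down_multiplier = 0.3,
                   viability_killed = character(),
                   killed_cell_multiplier = 0.3),
    cuts = list(up_cut = 1.5, down_cut = -1.5, viability_cut = -1.5),
    basal = "0mM"
  )
}

# per-stage sub-seed: one user seed, stage name hashed into an offset,
# kept below 2^31 so set.seed() accepts it
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L + sum(utf8ToInt(stage))
}

load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- utils::modifyList(cfg, user)
  }
  # JSON round-trips named vectors as lists; coerce the ones we index
  cfg$control_n <- unlist(cfg$control_n)
  cfg$noise$condition_fold <- unlist(cfg$noise$condition_fold)
  cfg
}

#' Run the whole screen pipeline
#'
#' Executes design -> simulate -> score -> integrate -> qc in order,
#' writing every stage's output under `out_dir` and a run manifest last.
#' Each stage draws from its own sub-seed derived from `seed`, so stages
#' are independently reproducible; re-running with the same seed and
#' config reproduces byte-identical outputs.
#'
#' @param config configuration list as from [default_config()]
#' @param seed master integer seed
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output and returns results only
#' @return (invisibly) list with all stage results and the manifest
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL) {
  t0 <- Sys.time()
  stage <- "design"
  res <- tryCatch({
    library <- if (is.null(config$library_path)) {
      synthetic_library(config$n_genes, nt_gene = config$nt_gene)
    } else {
      load_library(config$library_path)
    }
    design <- assign_wells(
      library,
      replicates = config$replicates, capacity = config$capacity,
      control_spec = default_control_spec(nt_n = config$nt_n,
                                          control_n = config$control_n,
                                          nt_gene = config$nt_gene),
      conditions = config$conditions,
      seed = stage_seed(seed, "design"),
      randomize_controls = config$randomize_controls)
    violations <- validate_layout(design)
    if (nrow(violations)) {
      stop("layout validation failed: ",
           paste(violations$violation, collapse = "; "), call. = FALSE)
    }
    picklist <- generate_picklist(design, library,
                                  volume_nl = config$volume_nl)

    stage <- "simulate"
    candidates <- library$gene_symbol[
      !library$gene_symbol %in% c(config$nt_gene, names(config$control_n))]
    effects <- plant_effects(
      candidates,
      n_up = config$effects$n_up, n_down = config$effects$n_down,
      up_multiplier = config$effects$up_multiplier,
      down_multiplier = config$effects$down_multiplier,
      viability_killed = config$effects$viability_killed,
      conditions = config$conditions,
      killed_cell_multiplier = config$effects$killed_cell_multiplier,
      seed = stage_seed(seed, "effects"),
      nt_gene = config$nt_gene)
    noise <- noise_config(
      well_cv = config$noise$well_cv, plate_sigma = config$noise$plate_sigma,
      base_signal = config$noise$base_signal,
      condition_fold = config$noise$condition_fold,
      base_cells = config$noise$base_cells, cell_cv = config$noise$cell_cv)
    measurements <- simulate_screen(design, effects, noise,
                                    seed = stage_seed(seed, "simulate"))

    stage <- "score"
    scores <- score_screen(measurements, design)

    stage <- "integrate"
    hits <- call_hits(scores,
                      up_cut = config$cuts$up_cut,
                      down_cut = config$cuts$down_cut,
                      viability_cut = config$cuts$viability_cut)
    venn <- integrate_conditions(hits)

    stage <- "qc"
    qc <- qc_controls(scores, measurements, design, basal = config$basal)

    list(library = library, design = design, picklist = picklist,
         effects = effects, measurements = measurements, scores = scores,
         hits = hits, venn = venn, qc = qc)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      layout = file.path(out_dir, "layout.csv"),
      picklist = file.path(out_dir, "picklist.csv"),
      effects = file.path(out_dir, "effects.csv"),
      measurements = file.path(out_dir, "measurements.csv"),
      scores = file.path(out_dir, "scores.csv"),
      hits = file.path(out_dir, "hits.csv"),
      venn = file.path(out_dir, "venn.json"),
      qc = file.path(out_dir, "qc.json"),
      summary = file.path(out_dir, "summary.md"))
    write_layout(res$design, paths[["layout"]])
    write_picklist(res$picklist, paths[["picklist"]],
                   zero_pad = isTRUE(config$zero_pad_wells))
    utils::write.csv(res$effects, paths[["effects"]], row.names = FALSE)
    utils::write.csv(res$measurements, paths[["measurements"]],
                     row.names = FALSE)
    utils::write.csv(res$scores, paths[["scores"]], row.names = FALSE)
    utils::write.csv(as.data.frame(res$hits), paths[["hits"]],
                     row.names = FALSE)
    jsonlite::write_json(res$venn, paths[["venn"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    jsonlite::write_json(list(controls = res$qc$controls,
                              fold_induction = res$qc$fold_induction,
                              all_pass = res$qc$all_pass,
                              viability_cut = config$cuts$viability_cut),
                         paths[["qc"]], auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    writeLines(render_summary(res), paths[["summary"]])

    manifest <- list(
      package_version = as.character(utils::packageVersion("gsisscreen")),
      created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed,
      stage_seeds = list(design = stage_seed(seed, "design"),
                         effects = stage_seed(seed, "effects"),
                         simulate = stage_seed(seed, "simulate")),
      config = config,
      outputs = as.list(stats::setNames(
        unname(tools::md5sum(paths)), names(paths)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }
  invisible(res)
}

#' Render a human-readable run summary
#'
#' @param results list returned by [run_pipeline()]
#' @return character vector of markdown lines
#' @export
render_summary <- function(results) {
  venn <- results$venn
  qc <- results$qc
  lines <- c("# Screen run summary", "",
             "## Hits per direction and condition", "")
  pc <- venn$per_condition
  lines <- c(lines, "| condition | up | down |",
             "|---|---|---|")
  for (cond in unique(pc$condition)) {
    up <- pc$count[pc$condition == cond & pc$direction == "up"]
    down <- pc$count[pc$condition == cond & pc$direction == "down"]
    lines <- c(lines, sprintf("| %s | %d | %d |", cond, up, down))
  }
  lines <- c(lines, "",
             sprintf("Union over conditions: %d up, %d down, %d hits total.",
                     venn$union$up, venn$union$down, venn$union$total),
             "")
  n_excl <- sum(results$hits$viability_excluded)
  lines <- c(lines, sprintf(
    "Viability filter excluded %d candidate gene(s) (secretion and cell-number beta both below cut-off in some condition).",
    n_excl), "")
  if (!is.null(qc)) {
    lines <- c(lines, "## Control QC", "",
               sprintf("%d/%d control expectations pass.",
                       sum(qc$controls$pass), nrow(qc$controls)), "",
               "## NT fold induction (mean over sets)", "")
    fi <- qc$fold_induction
    for (cond in unique(fi$condition)) {
      lines <- c(lines, sprintf("- %s: %.2f-fold", cond,
                                mean(fi$fold[fi$condition == cond])))
    }
  }
  lines
}
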
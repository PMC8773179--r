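# in-code fixtures: all test data is generated programmatically

# a small candidate library plus the NT/control entries, spread over
# `n_source_plates` source plates so picklist block structure is testable
small_library <- function(n_genes = 6, n_source_plates = 1) {
  ctrl <- c("NT", "INSULIN", "PLK1", "ZMIZ1", "HNF4A")
  genes <- c(ctrl, sprintf("G%03d", seq_len(n_genes)))
  n <- length(genes)
  plates <- sprintf("SRC%02d", rep_len(seq_len(n_source_plates), n))
  lib <- data.frame(
    uniprot_id = sprintf("U%05d", seq_len(n)),
    gene_symbol = genes,
    catalog_id = NA_character_,
    source_plate = plates,
    source_well = well_labels()[seq_len(n)],
    stringsAsFactors = FALSE
  )
  class(lib) <- c("sirna_library", "data.frame")
  lib
}

write_library_csv <- function(lib, path = tempfile(fileext = ".csv")) {
  utils::write.csv(lib, path, row.names = FALSE, na = "")
  path
}

# compact control spec so small designs fit comfortably on one plate
small_control_spec <- function(nt_n = 4L) {
  default_control_spec(nt_n = nt_n,
                       control_n = c(INSULIN = 2L, PLK1 = 2L,
                                     ZMIZ1 = 2L, HNF4A = 2L))
}

small_design <- function(n_genes = 6, seed = 7, replicates = 3L,
                         conditions = c("0mM", "20mM", "20mM+IBMX"),
                         nt_n = 4L) {
  assign_wells(small_library(n_genes), replicates = replicates,
               capacity = max(n_genes, 1L),
               control_spec = small_control_spec(nt_n),
               conditions = conditions, seed = seed)
}

noise_free <- function() {
  noise_config(well_cv = 0, plate_sigma = 0, cell_cv = 0)
}

# independent direct-arithmetic SSMD oracle (kept deliberately separate
# from the package implementation)
ssmd_oracle <- function(x1, x2) {
  (mean(x1) - mean(x2)) / sqrt(stats::var(x1) + stats::var(x2))
}
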
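#' Load an siRNA library table
#'
#' Reads the cherry-pick source library: one row per siRNA with its
#' UniProt accession, gene symbol and source-plate coordinates. Control
#' siRNAs (non-targeting and gene-targeting controls) live in the same
#' table so that picklist generation can resolve every destination well
#' to a source well.
#'
#' @param path CSV file with header columns `uniprot_id`, `gene_symbol`,
#'   `source_plate`, `source_well` (optional `catalog_id`)
#' @return data.frame of class `sirna_library`, source wells normalized
#'   to the unpadded dialect
#' @export
load_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("uniprot_id", "gene_symbol", "source_plate", "source_well")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols)) {
    stop("library CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"catalog_id" %in% names(lib)) lib$catalog_id <- NA_character_
  bad <- which(!is_valid_well(lib$source_well))
  if (length(bad)) {
    stop("malformed source_well in library row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(lib$source_well[bad]), collapse = ", "), call. = FALSE)
  }
  lib$source_well <- parse_well(lib$source_well)$well
  dup <- lib$uniprot_id[duplicated(lib$uniprot_id)]
  if (length(dup)) {
    stop("duplicate uniprot_id in library: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  lib <- lib[, c("uniprot_id", "gene_symbol", "catalog_id",
                 "source_plate", "source_well")]
  class(lib) <- c("sirna_library", "data.frame")
  lib
}

#' Default on-plate control well counts
#'
#' Every assay plate carries non-targeting (NT) siRNA wells as the SSMD
#' reference group plus four gene-targeting controls: INSULIN and PLK1
#' (negative secretion controls), ZMIZ1 (negative, strongest at low/high
#' glucose) and HNF4A (positive at high glucose). Counts default to 33 NT
#' wells and 8 wells per control gene.
#'
#' @param nt_n NT wells per plate
#' @param control_n named integer vector, wells per control gene
#' @param nt_gene gene symbol used for the non-targeting siRNA
#' @return data.frame with columns `role`, `gene_symbol`, `n_wells`
#' @export
default_control_spec <- function(nt_n = 33L,
                                 control_n = c(INSULIN = 8L, PLK1 = 8L,
                                               ZMIZ1 = 8L, HNF4A = 8L),
                                 nt_gene = "NT") {
  data.frame(
    role = c("nt", rep("control", length(control_n))),
    gene_symbol = c(nt_gene, names(control_n)),
    n_wells = as.integer(c(nt_n, control_n)),
    stringsAsFactors = FALSE
  )
}

#' Build randomized plate-set layouts
#'
#' Partitions the candidate genes into plate sets of at most `capacity`
#' genes (library order), reserves control wells on every plate, and
#' places each candidate gene `replicates` times at positions drawn
#' uniformly at random without replacement from the free wells. One
#' integer seed governs all placement, so a fixed (seed, inputs) pair
#' reproduces the layout exactly. Each set is physically replicated once
#' per assay condition; all condition plates of a set share the layout.
#'
#' @param library `sirna_library` (or data.frame with the same columns)
#' @param replicates wells per candidate gene within its set (default 3)
#' @param capacity max candidate genes per plate set (default 75, so a
#'   521-gene library yields 7 sets)
#' @param control_spec data.frame as from [default_control_spec()]
#' @param conditions character vector of assay condition labels; each
#'   gets its own replica plate per set
#' @param seed integer seed for well randomization
#' @param randomize_controls place control wells at random positions
#'   (default); `FALSE` pins them to the first free wells in row-major
#'   order for a fixed-position layout
#' @return object of class `plate_design`: list with `layout` (one row
#'   per well assignment), `condition_plates` (set x condition barcodes),
#'   and the design parameters
#' @export
assign_wells <- function(library,
                         replicates = 3L,
                         capacity = 75L,
                         control_spec = default_control_spec(),
                         conditions = c("0mM", "20mM", "20mM+IBMX"),
                         seed = 1L,
                         randomize_controls = TRUE) {
  replicates <- as.integer(replicates)
  capacity <- as.integer(capacity)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  ctrl_wells_total <- sum(control_spec$n_wells)
  if (capacity * replicates + ctrl_wells_total > PLATE_WELLS) {
    stop(sprintf(
      "capacity %d x %d replicates + %d control wells exceeds %d wells/plate",
      capacity, replicates, ctrl_wells_total, PLATE_WELLS), call. = FALSE)
  }
  if (anyDuplicated(conditions)) stop("duplicate condition labels", call. = FALSE)

  ctrl_genes <- control_spec$gene_symbol
  candidates <- library$gene_symbol[!library$gene_symbol %in% ctrl_genes]
  n_sets <- max(1L, ceiling(length(candidates) / capacity))

  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  all_wells <- well_labels()

  layout <- vector("list", n_sets)
  for (k in seq_len(n_sets)) {
    genes_k <- if (length(candidates))
      candidates[seq((k - 1L) * capacity + 1L,
                     min(length(candidates), k * capacity))]
    else character()
    # reserve control wells first, then draw candidate wells from the rest
    ctrl_rep <- rep(seq_len(nrow(control_spec)), control_spec$n_wells)
    n_ctrl <- length(ctrl_rep)
    if (randomize_controls) {
      ctrl_pos <- sample(all_wells, n_ctrl)
    } else {
      ctrl_pos <- all_wells[seq_len(n_ctrl)]
    }
    free <- setdiff(all_wells, ctrl_pos)
    n_cand_wells <- length(genes_k) * replicates
    cand_pos <- sample(free, n_cand_wells)
    empty_pos <- setdiff(free, cand_pos)

    dest <- sprintf("DP%03d", k)
    layout[[k]] <- data.frame(
      set_id = k,
      destination_plate = dest,
      well = c(ctrl_pos, cand_pos, empty_pos),
      role = c(control_spec$role[ctrl_rep],
               rep("candidate", n_cand_wells),
               rep("empty", length(empty_pos))),
      gene_symbol = c(control_spec$gene_symbol[ctrl_rep],
                      rep(genes_k, each = replicates),
                      rep(NA_character_, length(empty_pos))),
      replicate_index = c(
        sequence(control_spec$n_wells),
        rep(seq_len(replicates), times = length(genes_k)),
        rep(NA_integer_, length(empty_pos))),
      stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, layout)

  condition_plates <- expand.grid(set_id = seq_len(n_sets),
                                  condition = conditions,
                                  KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE)
  condition_plates <- condition_plates[order(condition_plates$set_id), ]
  condition_plates$plate <- sprintf("DP%03d_%s", condition_plates$set_id,
                                    condition_slug(condition_plates$condition))
  rownames(condition_plates) <- NULL

  structure(list(layout = layout,
                 condition_plates = condition_plates,
                 replicates = replicates,
                 capacity = capacity,
                 control_spec = control_spec,
                 conditions = conditions,
                 seed = seed),
            class = "plate_design")
}

#' @export
print.plate_design <- function(x, ...) {
  n_cand <- length(unique(x$layout$gene_symbol[x$layout$role == "candidate"]))
  cat(sprintf(
    "plate_design: %d candidate genes x %d replicates, %d set(s) x %d condition(s) = %d assay plates\n",
    n_cand, x$replicates, max(x$layout$set_id), length(x$conditions),
    max(x$layout$set_id) * length(x$conditions)))
  invisible(x)
}

#' Generate an acoustic-dispenser picklist
#'
#' One transfer row per non-empty destination well per condition-replica
#' plate. Rows are ordered by (source plate, source well) so that every
#' source plate is visited in a single contiguous block -- each source
#' plate is thawed exactly once.
#'
#' @param design `plate_design` from [assign_wells()]
#' @param library `sirna_library` resolving every gene to a source well
#' @param volume_nl transfer volume in nanolitres (default 100)
#' @return data.frame with columns `source_plate`, `source_well`,
#'   `destination_plate`, `destination_well`, `volume_nl`
#' @export
generate_picklist <- function(design, library, volume_nl = 100) {
  stopifnot(inherits(design, "plate_design"))
  if (volume_nl <= 0) stop("volume_nl must be > 0", call. = FALSE)
  lay <- design$layout[design$layout$role != "empty", , drop = FALSE]
  if (nrow(lay) == 0L) {
    return(data.frame(source_plate = character(), source_well = character(),
                      destination_plate = character(),
                      destination_well = character(),
                      volume_nl = numeric(), stringsAsFactors = FALSE))
  }
  idx <- match(lay$gene_symbol, library$gene_symbol)
  if (anyNA(idx)) {
    stop("gene(s) not found in library: ",
         paste(unique(lay$gene_symbol[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  cp <- design$condition_plates
  rows <- lapply(seq_len(nrow(cp)), function(i) {
    sel <- lay$set_id == cp$set_id[i]
    data.frame(source_plate = library$source_plate[idx[sel]],
               source_well = library$source_well[idx[sel]],
               destination_plate = cp$plate[i],
               destination_well = lay$well[sel],
               volume_nl = volume_nl,
               stringsAsFactors = FALSE)
  })
  pick <- do.call(rbind, rows)
  pick <- pick[order(pick$source_plate, well_order_key(pick$source_well),
                     pick$destination_plate,
                     well_order_key(pick$destination_well)), ]
  rownames(pick) <- NULL
  pick
}

#' Validate a plate-set layout
#'
#' Checks replicate completeness of every candidate gene, duplicate well
#' use, presence of every control role, genes split across sets, and
#' well-label validity. The report is empty if and only if the layout
#' satisfies all invariants.
#'
#' @param design `plate_design`
#' @return data.frame with columns `violation`, `set_id`, `detail`;
#'   zero rows for a valid layout
#' @export
validate_layout <- function(design) {
  lay <- design$layout
  out <- list()
  add <- function(violation, set_id, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      violation = violation, set_id = set_id, detail = detail,
      stringsAsFactors = FALSE)
  }

  bad_wells <- !is_valid_well(lay$well)
  for (i in which(bad_wells)) {
    add("invalid well label", lay$set_id[i], lay$well[i])
  }

  key <- paste(lay$destination_plate, lay$well)
  for (k in unique(key[duplicated(key)])) {
    add("duplicate well", lay$set_id[match(k, key)], k)
  }

  cand <- lay[lay$role == "candidate" & !is.na(lay$gene_symbol), ]
  counts <- table(cand$set_id, cand$gene_symbol)
  if (nrow(counts)) {
    per_gene_sets <- colSums(counts > 0)
    for (g in names(per_gene_sets[per_gene_sets > 1])) {
      add("gene split across sets", NA_integer_, g)
    }
    wrong <- which(counts != design$replicates & counts > 0, arr.ind = TRUE)
    if (nrow(wrong)) {
      for (i in seq_len(nrow(wrong))) {
        add("incomplete replicates",
            as.integer(rownames(counts)[wrong[i, 1]]),
            sprintf("%s has %d of %d wells",
                    colnames(counts)[wrong[i, 2]],
                    counts[wrong[i, 1], wrong[i, 2]], design$replicates))
      }
    }
  }

  for (s in unique(lay$set_id)) {
    present <- lay$gene_symbol[lay$set_id == s & lay$role %in% c("nt", "control")]
    miss <- setdiff(design$control_spec$gene_symbol, present)
    for (g in miss) add("missing control", s, g)
  }

  if (length(out)) do.call(rbind, out) else
    data.frame(violation = character(), set_id = integer(),
               detail = character(), stringsAsFactors = FALSE)
}

#' Write the layout as CSV
#'
#' @param design `plate_design`
#' @param path output file
#' @export
write_layout <- function(design, path) {
  utils::write.csv(design$layout, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a picklist in the ECHO Cherry Pick dialect
#'
#' Column headers follow the acoustic dispenser's import format:
#' Source Plate Barcode, Source Well, Destination Plate Barcode,
#' Destination Well, Transfer Volume (nL).
#'
#' @param picklist data.frame from [generate_picklist()]
#' @param path output file
#' @param zero_pad write zero-padded well labels ("A01")
#' @export
write_picklist <- function(picklist, path, zero_pad = FALSE) {
  out <- picklist
  if (zero_pad && nrow(out)) {
    pad <- function(w) {
      p <- parse_well(w)
      paste0(PLATE_ROWS[p$row], sprintf("%02d", p$col))
    }
    out$source_well <- pad(out$source_well)
    out$destination_well <- pad(out$destination_well)
  }
  names(out) <- c("Source Plate Barcode", "Source Well",
                  "Destination Plate Barcode", "Destination Well",
                  "Transfer Volume")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
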
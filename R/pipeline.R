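# Config-driven end-to-end pipeline: annotate -> scaffold -> classify ->
# phylo -> dnds -> massmatch -> compare, each stage optional. One validated
# config object (yaml-loadable list) describes a reproducible run.

PIPELINE_STAGES <- c("annotate", "scaffold", "classify", "phylo", "dnds",
                     "massmatch", "compare")

validate_pipeline_config <- function(config) {
  known <- c("input", "simulate", "stages", "id_threshold", "mass_tol",
             "mass_mode", "seed", "output_dir", "correction", "reps")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$input)) {
    unknown_in <- setdiff(names(config$input), c("proteins", "masses"))
    if (length(unknown_in) > 0L) {
      abort(paste0("unknown input key(s): ", paste(unknown_in, collapse = ", ")))
    }
  }
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0L) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  idt <- config$id_threshold %||% 0.40
  if (idt < 0 || idt > 1) abort("id_threshold must be in [0, 1]")
  tol <- config$mass_tol %||% 0.5
  if (tol <= 0) abort("mass_tol must be > 0")
  if (is.null(config$input) && is.null(config$simulate)) {
    abort("config needs either 'input' paths or a 'simulate' section")
  }
  invisible(TRUE)
}

#' Run the CRP analysis pipeline from a config
#'
#' Chains annotation, scaffold classification, family clustering, phylogeny,
#' region-wise selection, mass matching and trend summaries over one input
#' set. The config is a plain list (e.g. loaded with [yaml::read_yaml()]):
#' unknown keys are rejected before any work is done.
#'
#' Config keys: `input` (list with `proteins` FASTA path and optional
#' `masses` CSV path with an `m` column), or `simulate` (`TRUE` or a list
#' passed to [crp_generator_spec()]); `stages` (subset of annotate, scaffold,
#' classify, phylo, dnds, massmatch, compare); `id_threshold`; `mass_tol`;
#' `mass_mode`; `correction`; `reps` (bootstrap replicates); `seed`;
#' `output_dir` (when set, CSV/newick outputs and a run log are written).
#'
#' @param config Named list (or path to a yaml file).
#' @return A named list bundle with one element per executed stage.
#' @export
run_crp_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  stages <- config$stages %||% PIPELINE_STAGES
  seed <- config$seed %||% 1L
  log_lines <- c(
    paste0("venomcrp ", as.character(utils::packageVersion("venomcrp"))),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ",")),
    paste0("id_threshold: ", config$id_threshold %||% 0.40),
    paste0("mass_tol: ", config$mass_tol %||% 0.5)
  )
  say <- function(stage, msg) {
    line <- paste0("[", stage, "] ", msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }

  bundle <- list()
  masses <- NULL
  if (!is.null(config$input)) {
    records <- read_fasta(config$input$proteins)
    if (!is.null(config$input$masses)) {
      masses <- utils::read.csv(config$input$masses)$m
    }
    say("input", paste0(nrow(records), " records from ", config$input$proteins))
  } else {
    simconf <- config$simulate
    gspec <- if (isTRUE(simconf)) {
      crp_generator_spec(seed = seed)
    } else {
      do.call(crp_generator_spec, c(list(seed = seed), simconf))
    }
    sim <- simulate_crp_dataset(gspec)
    bundle$truth <- sim$truth
    records <- sim$proteins
    say("input", paste0(nrow(records), " simulated records (seed ", seed, ")"))
  }

  ann <- records
  if ("annotate" %in% stages) {
    ann <- tryCatch(annotate_precursors(records), error = function(e) fail("annotate", e))
    bundle$annotation <- ann
    say("annotate", paste0(sum(!is.na(ann$propeptide_start)),
                           " of ", nrow(ann), " precursors carry a propeptide"))
  }
  if ("scaffold" %in% stages) {
    ann <- tryCatch(classify_scaffolds(ann), error = function(e) fail("scaffold", e))
    bundle$annotation <- ann
    say("scaffold", paste0(length(unique(ann$framework)), " distinct frameworks"))
  }
  fams <- NULL
  if ("classify" %in% stages) {
    fams <- tryCatch(
      classify_families(ann, id_threshold = config$id_threshold %||% 0.40),
      error = function(e) fail("classify", e)
    )
    ann <- as_tibble(fams)
    bundle$families <- fams
    say("classify", paste0(nrow(attr(fams, "families")), " families"))
  }
  if ("phylo" %in% stages) {
    ph <- tryCatch(crp_phylo(ann, correction = config$correction %||% "poisson"),
                   error = function(e) fail("phylo", e))
    bundle$phylo <- ph
    say("phylo", paste0("NJ tree with ", length(ph$tree$tip.label), " leaves"))
  }
  if ("dnds" %in% stages && "cdna" %in% names(ann)) {
    fam_col <- if ("family" %in% names(ann)) ann$family else rep(1L, nrow(ann))
    sel <- purrr::map(split(seq_len(nrow(ann)), fam_col), function(ix) {
      sub <- ann[ix, ]
      cds <- sub("TAA$|TAG$|TGA$", "", sub$cdna)
      if (length(ix) < 2L || length(unique(nchar(cds))) != 1L) return(NULL)
      aln <- codon_alignment(sub$id, cds,
                             regions = region_labels_from_annotation(sub[1L, ]))
      out <- tryCatch(
        region_selection(aln, reps = config$reps %||% 1000L, seed = seed),
        error = function(e) NULL
      )
      if (!is.null(out)) out$family <- fam_col[ix[1L]]
      out
    }) |> dplyr::bind_rows()
    bundle$selection <- sel
    say("dnds", paste0(nrow(sel), " region x family estimates"))
  }
  if ("massmatch" %in% stages) {
    if (is.null(masses) && is.null(config$input)) {
      mm <- gen_mass_observations(ann, noise_sd = 0.1,
                                  n_decoys = 30L, seed = seed + 1L)
      masses <- mm$observations$m
      bundle$mass_truth <- mm$truth
    }
    if (!is.null(masses)) {
      bundle$mass_matches <- match_masses(
        ann, masses, tol = config$mass_tol %||% 0.5,
        mode = config$mass_mode %||% "monoisotopic"
      )
      say("massmatch", paste0(nrow(bundle$mass_matches), " matches at tol ",
                              config$mass_tol %||% 0.5, " Da"))
    }
  }
  if ("compare" %in% stages) {
    bundle$trends <- list(
      propeptide = propeptide_bins(ann, species = "dataset"),
      cysteines = cys_count_classes(ann, species = "dataset"),
      inventory = scaffold_inventory(list(dataset = ann))
    )
    say("compare", "trend tables computed")
  }

  outdir <- config$output_dir
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(bundle$annotation)) {
      write_family_report(bundle$annotation, file.path(outdir, "annotation.csv"))
    }
    if (!is.null(bundle$families)) {
      write.csv(attr(bundle$families, "families"),
                file.path(outdir, "families.csv"), row.names = FALSE)
      write.csv(tidy(bundle$families),
                file.path(outdir, "assignments.csv"), row.names = FALSE)
    }
    if (!is.null(bundle$phylo)) {
      writeLines(newick(bundle$phylo), file.path(outdir, "tree.nwk"))
    }
    if (!is.null(bundle$selection)) {
      write.csv(bundle$selection, file.path(outdir, "selection.csv"),
                row.names = FALSE)
    }
    if (!is.null(bundle$mass_matches)) {
      write.csv(bundle$mass_matches, file.path(outdir, "mass_matches.csv"),
                row.names = FALSE)
    }
    if (!is.null(bundle$trends)) {
      write.csv(bundle$trends$inventory, file.path(outdir, "scaffold_inventory.csv"),
                row.names = FALSE)
    }
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }
  bundle
}

# Per-codon region labels from one annotated row (protein coordinates map to
# codons 1:1 because the CDS is in frame with the precursor).
region_labels_from_annotation <- function(row) {
  n <- nchar(row$protein)
  lab <- rep("mature", n)
  lab[seq_len(row$signal_end)] <- "signal"
  if (!is.na(row$propeptide_start)) {
    lab[(row$propeptide_start + 1L):row$propeptide_end] <- "propeptide"
  }
  if (!is.na(row$cterm_start)) {
    lab[(row$cterm_start + 1L):row$cterm_end] <- "cterm"
  }
  lab
}
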
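## End-to-end workflow: pairing -> D/D scaffold -> L/L by mirror -> L/D by
## per-strand enantiomerization + restrained refinement -> D/L by mirror of
## L/D -> chirality validation -> conformational reports -> optional
## ensemble analyses -> heavy-atom accounting. All outputs are plain text
## (PDB, CSV, JSON) plus a machine-readable manifest; deterministic under
## the config seed.

#' Pipeline configuration
#'
#' @param ribozyme,substrate sequences, 5' to 3'.
#' @param helix_form `"A"` or `"B"` for the stems.
#' @param mirror_strand which strand is enantiomerized for the heterochiral
#'   complexes: `"substrate"` (L-RNA/D-Rz) or `"ribozyme"`.
#' @param refine_settings a [refinement_settings()] for the heterochiral
#'   conversion.
#' @param ensemble an [ensemble_spec()] to enable the ensemble stage, or
#'   `NULL` to skip it.
#' @param outdir output directory (created).
#' @param seed root seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(ribozyme, substrate, helix_form = "A",
                            mirror_strand = c("substrate", "ribozyme"),
                            refine_settings = NULL,
                            ensemble = NULL, outdir = tempfile("hhrun"),
                            seed = 1L) {
  mirror_strand <- match.arg(mirror_strand)
  structure(list(ribozyme = ribozyme, substrate = substrate,
                 helix_form = helix_form, mirror_strand = mirror_strand,
                 refine_settings = refine_settings, ensemble = ensemble,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path config file whose fields match [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$ensemble)) cfg$ensemble <- do.call(ensemble_spec, cfg$ensemble)
  do.call(pipeline_config, cfg)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full chirality-aware modelling workflow
#'
#' Stages: (1) pairing map and cleavage site; (2) all-D scaffold; (3) L/L
#' homochiral complex by mirror; (4) heterochiral complex by strand
#' enantiomerization plus restrained refinement; (5) its mirror image;
#' (6) chirality validation of all four; (7) conformational records,
#' angle-difference profiles, circular summary with mirror-symmetry
#' checks; (8) optional ensemble generation with conformer-distribution
#' and per-region RMSD-series analyses; (9) heavy-atom accounting. A
#' manifest (JSON) lists every artifact; any stage error aborts with the
#' stage name after persisting the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list; also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = list(
    ribozyme = config$ribozyme, substrate = config$substrate,
    helix_form = config$helix_form, mirror_strand = config$mirror_strand,
    seed = config$seed))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(...) file.path(config$outdir, ...)
  ## (1) pairing
  pm <- stage("pairing", hammerhead_pairing(config$ribozyme, config$substrate))
  manifest$cleavage_site <- pm$cleavage_site
  manifest$helix_pairs <- as.list(table(pm$pairs$helix))
  write_csv(pm$pairs, out("pairing.csv"))
  writeLines(pairing_to_dotbracket(pm), out("pairing.dotbracket"))
  ## (2) D/D scaffold
  dd <- stage("scaffold", build_hammerhead_scaffold(
    config$ribozyme, config$substrate, pm, form = helix_form(config$helix_form)))
  ## (3) L/L by mirror
  ll <- stage("mirror_ll", mirror_structure(dd))
  ## (4) heterochiral by enantiomerization + refinement
  strand <- if (config$mirror_strand == "substrate") pm$chains[2] else pm$chains[1]
  settings <- config$refine_settings
  if (is.null(settings)) {
    settings <- refinement_settings(steps = 300, k_anchor = 0.5,
                                    k_hbond = 50, k_planarity = 10)
  }
  het <- stage("heterochiral", build_heterochiral(dd, strand, pm, settings))
  ## (5) mirror of the heterochiral complex
  het_m <- stage("mirror_heterochiral", mirror_structure(het))
  complexes <- if (config$mirror_strand == "substrate") {
    list("D/D" = dd, "L/L" = ll, "L/D" = het, "D/L" = het_m)
  } else {
    list("D/D" = dd, "L/L" = ll, "D/L" = het, "L/D" = het_m)
  }
  files <- c("D/D" = "complex_dd.pdb", "L/L" = "complex_ll.pdb",
             "L/D" = "complex_ld.pdb", "D/L" = "complex_dl.pdb")
  for (lb in names(complexes)) {
    write_pdb(complexes[[lb]], out(files[[lb]]))
  }
  manifest$complexes <- as.list(files)
  ## (6) chirality validation
  verdicts <- list()
  for (lb in names(complexes)) {
    rep <- stage("chirality_validation", validate_chirality(complexes[[lb]]))
    verdicts[[lb]] <- rep$verdict
    write_chirality_report(rep, out(paste0("chirality_",
                                           gsub("/", "", lb), ".json")))
  }
  manifest$chirality_verdicts <- verdicts
  ## (7) conformational reports
  stage("conformation_reports", {
    for (lb in names(complexes)) {
      write_csv(conformation_table(complexes[[lb]]),
                out(paste0("conformation_", gsub("/", "", lb), ".csv")))
    }
    prof <- torsion_difference_profile(complexes[[3]], complexes[[1]])
    write_csv(prof, out("angle_differences_het_vs_dd.csv"))
    cs <- circular_summary(complexes,
                           mirror_pairs = list(c("D/D", "L/L"),
                                               c("L/D", "D/L")))
    write_csv(cs, out("circular_summary.csv"))
    write_csv(attr(cs, "symmetry"), out("mirror_symmetry.csv"))
    manifest$mirror_symmetry <- attr(cs, "symmetry")$verdict
  })
  ## (8) optional ensemble analyses
  if (!is.null(config$ensemble)) {
    stage("ensemble", {
      spec <- config$ensemble
      spec$seed <- config$seed + 1000L
      ens <- generate_ensemble(dd, spec)
      write_pdb(ens, out("ensemble_dd.pdb"))
      write_csv(conformer_distribution(ens), out("conformer_distribution.csv"))
      regions <- pairing_regions(pm)
      write_csv(region_rmsd_series(ens, regions), out("region_rmsd_series.csv"))
      manifest$ensemble_frames <- spec$n_models
    })
  }
  ## (9) heavy-atom accounting
  counts <- stage("atom_accounting", {
    data.frame(
      selection = c("substrate", "ribozyme", "complex"),
      template_count = c(count_heavy_atoms(config$substrate),
                         count_heavy_atoms(config$ribozyme),
                         count_heavy_atoms(c(config$ribozyme, config$substrate))),
      built_count = c(sum(dd$atoms$chain == pm$chains[2]),
                      sum(dd$atoms$chain == pm$chains[1]),
                      nrow(dd$atoms)))
  })
  write_csv(counts, out("heavy_atoms.csv"))
  manifest$heavy_atoms <- stats::setNames(as.list(counts$template_count),
                                          counts$selection)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Named atom selections for the standard hammerhead regions
#'
#' Regions: helix1, helix2, helix3, core (unpaired residues), substrate,
#' ribozyme, all -- as selection lists for [region_rmsd_series()].
#'
#' @param pairing a `pairing_map`.
#' @return named list of selections.
#' @export
pairing_regions <- function(pairing) {
  pr <- pairing$pairs
  chR <- pairing$chains[1]; chS <- pairing$chains[2]
  reg_of <- function(h) {
    p <- pr[pr$helix == h, ]
    sel <- list()
    for (side in 1:2) {
      ch <- p[[paste0("chain", side)]]
      ri <- p[[paste0("resi", side)]]
      for (u in unique(ch)) sel[[u]] <- sort(unique(c(sel[[u]], ri[ch == u])))
    }
    list(resi = sel)
  }
  core <- split(pairing$unpaired$resi, pairing$unpaired$chain)
  list(helix1 = reg_of("H1"), helix2 = reg_of("H2"), helix3 = reg_of("H3"),
       core = list(resi = core),
       substrate = list(chain = chS),
       ribozyme = list(chain = chR),
       all = NULL)
}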
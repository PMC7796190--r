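## Seeded synthetic ensembles: coordinate-noise perturbation and per-residue
## resampling of sugar pucker (P) and glycosidic chi from prescribed wrapped
## normal distributions -- a statistical emulator for MD-like conformer
## ensembles, not a physical simulation.

#' Perturb a structure with i.i.d. Gaussian coordinate noise
#'
#' @param x an `rna_structure`.
#' @param sigma per-coordinate standard deviation, Angstrom (>= 0).
#' @param seed integer seed; the same (input, sigma, seed) gives a bitwise
#'   identical result.
#' @return perturbed `rna_structure`.
#' @export
perturb <- function(x, sigma, seed) {
  stopifnot(inherits(x, "rna_structure"), sigma >= 0)
  if (sigma == 0) return(x)
  xyz <- coords(x)
  rng <- local_rng(seed)
  noise <- matrix(rng$rnorm(length(xyz), 0, sigma), ncol = 3)
  coords(x) <- xyz + noise
  x
}

## Seeded RNG confined to a closure: no global state touched.
local_rng <- function(seed) {
  env <- new.env()
  local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(rnorm = function(...) draw(stats::rnorm, ...))
}

#' Specification of a synthetic conformer ensemble
#'
#' @param n_models number of frames (>= 1).
#' @param P_mean,P_sd per-residue pseudorotation phase mean and sd, degrees
#'   (scalars are recycled; `P_mean = NULL` keeps each residue's current
#'   phase as its mean).
#' @param chi_mean,chi_sd glycosidic chi mean and sd, degrees (same
#'   conventions).
#' @param noise_sd additional i.i.d. coordinate noise, Angstrom.
#' @param seed integer seed; identical spec and input give identical output.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 200, P_mean = NULL, P_sd = 8,
                          chi_mean = NULL, chi_sd = 10,
                          noise_sd = 0.05, seed = 1L) {
  stopifnot(n_models >= 1, all(P_sd >= 0), all(chi_sd >= 0), noise_sd >= 0)
  structure(list(n_models = as.integer(n_models), P_mean = P_mean,
                 P_sd = P_sd, chi_mean = chi_mean, chi_sd = chi_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Read an ensemble spec from a JSON or YAML config block
#' @param path JSON or YAML file with fields of [ensemble_spec()].
#' @return an `ensemble_spec`.
#' @export
read_ensemble_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(ensemble_spec, cfg)
}

#' Generate a seeded multi-model ensemble with prescribed conformer statistics
#'
#' Each frame resamples every residue's sugar pucker phase from a wrapped
#' normal (mean, sd per residue) and its glycosidic chi likewise, rebuilds
#' the residue parametrically, re-anchors it on its (fixed) base, and adds
#' optional coordinate noise. Deterministic under the spec seed.
#'
#' @param x an `rna_structure` (frame-0 topology and base positions).
#' @param spec an [ensemble_spec()].
#' @return an `rna_ensemble` with `spec$n_models` frames.
#' @export
generate_ensemble <- function(x, spec) {
  stopifnot(inherits(x, "rna_structure"), inherits(spec, "ensemble_spec"))
  rt <- residue_table(x)
  nres <- nrow(rt)
  cur <- conformation_table(x)
  key <- paste(cur$chain, cur$resi)
  ord <- match(paste(rt$chain, rt$resi), key)
  P_mean <- if (is.null(spec$P_mean)) cur$P[ord] else rep_len(spec$P_mean, nres)
  chi_mean <- if (is.null(spec$chi_mean)) cur$chi[ord] else rep_len(spec$chi_mean, nres)
  gamma_cur <- ifelse(is.na(cur$gamma[ord]), 54, cur$gamma[ord])
  beta_cur <- ifelse(is.na(cur$beta[ord]), 178, cur$beta[ord])
  numax_cur <- ifelse(is.na(cur$numax[ord]), 38, cur$numax[ord])
  if (anyNA(P_mean) || anyNA(chi_mean)) {
    bad <- which(is.na(P_mean) | is.na(chi_mean))[1]
    stop("generation error: undefined P or chi at residue ",
         rt$chain[bad], rt$resi[bad], " and no prescribed mean")
  }
  P_sd <- rep_len(spec$P_sd, nres)
  chi_sd <- rep_len(spec$chi_sd, nres)
  rng <- local_rng(spec$seed)
  frames <- vector("list", spec$n_models)
  for (f in seq_len(spec$n_models)) {
    fr <- x
    for (r in seq_len(nres)) {
      P_r <- wrap360(rng$rnorm(1, P_mean[r], P_sd[r]))
      chi_r <- wrap180(rng$rnorm(1, chi_mean[r], chi_sd[r]))
      fr <- rebuild_residue(fr, rt$chain[r], rt$resi[r], P = P_r,
                            numax = numax_cur[r], chi = chi_r,
                            gamma = gamma_cur[r], beta = beta_cur[r])
    }
    if (spec$noise_sd > 0) {
      xyz <- coords(fr)
      xyz <- xyz + matrix(rng$rnorm(length(xyz), 0, spec$noise_sd), ncol = 3)
      coords(fr) <- xyz
    }
    frames[[f]] <- fr
  }
  rna_ensemble(frames)
}

## Rebuild one residue at a new (P, chi), keeping its base fixed: the
## parametric nucleotide is fitted rigidly onto the existing base atoms.
rebuild_residue <- function(x, chain, resi, P, numax, chi, gamma, beta) {
  res <- residue_atoms(x, chain, resi)
  code <- res$resn[1]
  with_p <- "P" %in% res$name
  loc <- build_nucleotide(code, P = P, numax = numax, chi = chi,
                          gamma = gamma, beta = beta, with_phosphate = with_p)
  anchor <- c(residue_templates()[[code]]$base_atoms, "C1'")
  tgt <- residue_xyz(x, chain, resi, anchor)
  fit <- kabsch_superpose(loc[anchor, , drop = FALSE], tgt)
  placed <- xform(loc, fit$rotation, fit$translation)
  sel <- which(x$atoms$chain == chain & x$atoms$resi == resi)
  idx <- match(x$atoms$name[sel], rownames(placed))
  keep <- !is.na(idx)
  x$atoms[sel[keep], c("x", "y", "z")] <- placed[idx[keep], , drop = FALSE]
  x
}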
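## Torsion/improper parameter tables in an frcmod-like text dialect, their
## enantiomerization (negation of every chirality-defining signed parameter:
## torsion/improper phase, harmonic improper equilibrium), and a torsion
## energy evaluator used to demonstrate mirror-energy invariance.

#' Parse an frcmod-like parameter file
#'
#' Dialect: whitespace-separated records under `DIHE` and `IMPROPER`
#' section headers. A `DIHE` record is `T1-T2-T3-T4 idivf k phase n`;
#' an `IMPROPER` record is `T1-T2-T3-T4 k phase n` (periodic form, center
#' atom third by convention) or `T1-T2-T3-T4 harm k xi0` (harmonic form
#' `k (xi - xi0)^2` with k in kcal/mol rad^-2 and xi0 in degrees). Other
#' sections are preserved verbatim for round-tripping.
#'
#' @param path parameter file.
#' @return object of class `parameter_set`: list with `torsions`,
#'   `impropers` (data frames), `label` (`"D"` or `"L"`), `other_sections`.
#' @export
parse_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  headers <- c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER", "NONB", "NONBON")
  section <- NA_character_
  tors <- list(); impr <- list(); other <- list()
  title <- if (length(lines) && !trimws(lines[1]) %in% headers &&
               !grepl("^\\s*$", lines[1])) lines[1] else NULL
  start <- if (is.null(title)) 1L else 2L
  seen_section <- FALSE
  for (i in seq(start, length.out = max(0, length(lines) - start + 1L))) {
    ln <- lines[i]
    t <- trimws(ln)
    if (t %in% headers) {
      section <- t
      seen_section <- TRUE
      if (!section %in% c("DIHE", "IMPROPER")) other[[section]] <- character(0)
      next
    }
    if (t == "" || is.na(section)) next
    tok <- strsplit(t, "\\s+")[[1]]
    if (section == "DIHE") {
      if (length(tok) < 5) stop("parse error at line ", i, ": DIHE record needs 5 fields")
      num <- suppressWarnings(as.numeric(tok[2:5]))
      if (anyNA(num)) stop("parse error at line ", i, ": malformed numeric field")
      if (num[4] < 1 || num[4] > 6 || num[4] != round(num[4])) {
        stop("parse error at line ", i, ": periodicity must be an integer in 1..6")
      }
      tors[[length(tors) + 1L]] <- data.frame(
        types = tok[1], idivf = num[1], k = num[2], phase = wrap360(num[3]),
        periodicity = as.integer(num[4]), stringsAsFactors = FALSE)
    } else if (section == "IMPROPER") {
      if (length(tok) >= 2 && tok[2] == "harm") {
        num <- suppressWarnings(as.numeric(tok[3:4]))
        if (length(tok) < 4 || anyNA(num)) {
          stop("parse error at line ", i, ": malformed harmonic improper")
        }
        impr[[length(impr) + 1L]] <- data.frame(
          types = tok[1], form = "harmonic", k = num[1], phase = num[2],
          periodicity = NA_integer_, stringsAsFactors = FALSE)
      } else {
        if (length(tok) < 4) stop("parse error at line ", i, ": IMPROPER record needs 4 fields")
        num <- suppressWarnings(as.numeric(tok[2:4]))
        if (anyNA(num)) stop("parse error at line ", i, ": malformed numeric field")
        impr[[length(impr) + 1L]] <- data.frame(
          types = tok[1], form = "periodic", k = num[1], phase = wrap360(num[2]),
          periodicity = as.integer(num[3]), stringsAsFactors = FALSE)
      }
    } else {
      other[[section]] <- c(other[[section]], ln)
    }
  }
  if (!seen_section) stop("parse error: no section headers (DIHE/IMPROPER) found")
  structure(list(
    title = title,
    torsions = if (length(tors)) do.call(rbind, tors) else
      data.frame(types = character(0), idivf = numeric(0), k = numeric(0),
                 phase = numeric(0), periodicity = integer(0)),
    impropers = if (length(impr)) do.call(rbind, impr) else
      data.frame(types = character(0), form = character(0), k = numeric(0),
                 phase = numeric(0), periodicity = integer(0)),
    label = "D", other_sections = other), class = "parameter_set")
}

#' Write a parameter set in the frcmod-like dialect
#' @param params a `parameter_set`.
#' @param path output file.
#' @export
write_parameters <- function(params, path) {
  out <- character(0)
  if (!is.null(params$title)) out <- c(out, params$title)
  for (s in names(params$other_sections)) {
    out <- c(out, s, params$other_sections[[s]], "")
  }
  out <- c(out, "DIHE")
  t <- params$torsions
  for (i in seq_len(nrow(t))) {
    out <- c(out, sprintf("%s %g %g %g %d", t$types[i], t$idivf[i], t$k[i],
                          t$phase[i], t$periodicity[i]))
  }
  out <- c(out, "", "IMPROPER")
  im <- params$impropers
  for (i in seq_len(nrow(im))) {
    out <- c(out, if (im$form[i] == "harmonic") {
      sprintf("%s harm %g %g", im$types[i], im$k[i], im$phase[i])
    } else {
      sprintf("%s %g %g %d", im$types[i], im$k[i], im$phase[i],
              im$periodicity[i])
    })
  }
  writeLines(out, path)
  invisible(path)
}

#' Derive L-nucleotide parameters from D parameters (or back)
#'
#' Negates the chirality-defining signed parameter of every term: the phase
#' of each periodic torsion and improper maps to `(-phase) mod 360` (so 0
#' and 180 are fixed points) and the signed equilibrium `xi0` of each
#' harmonic improper changes sign. Force constants and periodicities are
#' unchanged; the provenance label flips. The operation is an involution,
#' and the torsion-plus-improper energy is exactly invariant under
#' simultaneous structure mirroring and parameter enantiomerization.
#'
#' @param params a `parameter_set`.
#' @return the enantiomerized `parameter_set`.
#' @export
enantiomerize <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  params$torsions$phase <- wrap360(-params$torsions$phase)
  per <- params$impropers$form == "periodic"
  params$impropers$phase[per] <- wrap360(-params$impropers$phase[per])
  params$impropers$phase[!per] <- -params$impropers$phase[!per]
  params$label <- if (identical(params$label, "D")) "L" else "D"
  params
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> label ", x$label, ": ", nrow(x$torsions),
      " torsion term(s), ", nrow(x$impropers), " improper term(s)\n", sep = "")
  invisible(x)
}

#' Map structure atom quadruples to parameter terms
#'
#' Builds the assignment consumed by [torsion_energy()]: one row per
#' quadruple, referencing atoms by chain/residue/name and a term by kind
#' and row index in the parameter set.
#'
#' @param quads data frame with columns `chain1`, `resi1`, `name1`, ...,
#'   `chain4`, `resi4`, `name4`.
#' @param kind `"torsion"` or `"improper"` per row (recycled).
#' @param term row index into the corresponding parameter table (recycled).
#' @return data frame of class `torsion_assignment`.
#' @export
torsion_assignment <- function(quads, kind, term) {
  quads$kind <- rep_len(kind, nrow(quads))
  quads$term <- rep_len(as.integer(term), nrow(quads))
  class(quads) <- c("torsion_assignment", class(quads))
  quads
}

## All defined backbone + glycosidic torsion quadruples of a structure, as
## an assignment-ready quadruple table (used by tests and the pipeline).
structure_torsion_quads <- function(x) {
  defs <- list(
    alpha = list(c("O3'", -1L), c("P", 0L), c("O5'", 0L), c("C5'", 0L)),
    beta = list(c("P", 0L), c("O5'", 0L), c("C5'", 0L), c("C4'", 0L)),
    gamma = list(c("O5'", 0L), c("C5'", 0L), c("C4'", 0L), c("C3'", 0L)),
    delta = list(c("C5'", 0L), c("C4'", 0L), c("C3'", 0L), c("O3'", 0L)),
    epsilon = list(c("C4'", 0L), c("C3'", 0L), c("O3'", 0L), c("P", 1L)),
    zeta = list(c("C3'", 0L), c("O3'", 0L), c("P", 1L), c("O5'", 1L)))
  rt <- residue_table(x)
  rows <- list()
  has_atom <- function(chain, resi, name) {
    any(x$atoms$chain == chain & x$atoms$resi == resi & x$atoms$name == name)
  }
  for (k in seq_len(nrow(rt))) {
    ch <- rt$chain[k]; ri <- rt$resi[k]; code <- rt$resn[k]
    cand <- defs
    cand$chi <- list(c("O4'", 0L), c("C1'", 0L),
                     c(glyc_n(code), 0L),
                     c(if (is_purine(code)) "C4" else "C2", 0L))
    for (nm in names(cand)) {
      q <- cand[[nm]]
      ok <- all(vapply(q, function(a) has_atom(ch, ri + as.integer(a[2]), a[1]),
                       logical(1)))
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        torsion = nm,
        chain1 = ch, resi1 = ri + as.integer(q[[1]][2]), name1 = q[[1]][1],
        chain2 = ch, resi2 = ri + as.integer(q[[2]][2]), name2 = q[[2]][1],
        chain3 = ch, resi3 = ri + as.integer(q[[3]][2]), name3 = q[[3]][1],
        chain4 = ch, resi4 = ri + as.integer(q[[4]][2]), name4 = q[[4]][1],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Torsion + improper energy of a structure under a parameter set
#'
#' Proper terms contribute `(k / idivf) (1 + cos(n phi - delta))`; periodic
#' impropers `k (1 + cos(n xi - delta))`; harmonic impropers
#' `k (xi - xi0)^2` with the deviation wrapped to (-180, 180] and taken in
#' radians. A pure function of the coordinates and parameters.
#'
#' @param x an `rna_structure`.
#' @param params a `parameter_set`.
#' @param assignment a [torsion_assignment()].
#' @return energy, kcal/mol.
#' @export
torsion_energy <- function(x, params, assignment) {
  if (nrow(assignment) == 0) return(0)
  getxyz <- function(j) {
    ch <- assignment[[paste0("chain", j)]]
    ri <- assignment[[paste0("resi", j)]]
    nm <- assignment[[paste0("name", j)]]
    idx <- match(paste(ch, ri, nm), paste(x$atoms$chain, x$atoms$resi, x$atoms$name))
    if (anyNA(idx)) {
      k <- which(is.na(idx))[1]
      stop("assignment error: atom ", ch[k], ri[k], "/", nm[k], " not found")
    }
    coords(x)[idx, , drop = FALSE]
  }
  phi <- dihedral_rows(getxyz(1), getxyz(2), getxyz(3), getxyz(4))
  e <- 0
  for (r in seq_len(nrow(assignment))) {
    kind <- assignment$kind[r]
    ti <- assignment$term[r]
    if (kind == "torsion") {
      tm <- params$torsions[ti, ]
      if (is.na(tm$k)) stop("assignment error: no torsion term ", ti)
      e <- e + (tm$k / tm$idivf) *
        (1 + cos((tm$periodicity * phi[r] - tm$phase) / DEG))
    } else {
      tm <- params$impropers[ti, ]
      if (is.na(tm$k)) stop("assignment error: no improper term ", ti)
      if (tm$form == "periodic") {
        e <- e + tm$k * (1 + cos((tm$periodicity * phi[r] - tm$phase) / DEG))
      } else {
        e <- e + tm$k * (wrap180(phi[r] - tm$phase) / DEG)^2
      }
    }
  }
  e
}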
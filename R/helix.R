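## Ideal regular duplex generator. Bases are placed on dyad-symmetrized
## ideal Watson-Crick pairs carried along a helical screw; the sugar and
## backbone of each residue are built parametrically (pucker, chi, gamma,
## beta) and attached by an exact rigid fit on the base. Fiber-style
## helical parameters are pinned per form; the x-displacement of the pair
## from the helix axis is a pinned placement parameter calibrated once so
## that the canonical adjacent P-P distances (5.9 A for A-form/C3'-endo,
## 7.0 A for B-form/C2'-endo) emerge.

#' Helical form parameters
#'
#' Pinned generator parameters of the two supported regular forms.
#' A-form: twist 32.7 deg/step, rise 2.81 A/step, C3'-endo sugars (P = 18),
#' chi = -158. B-form: twist 36.0, rise 3.38, C2'-endo sugars (P = 162),
#' chi = -102.
#'
#' @param name `"A"` or `"B"`.
#' @return list of class `helix_form` with twist (deg/step), rise (A/step),
#'   target pucker phase `P`, amplitude `numax`, glycosidic `chi`, backbone
#'   `gamma` and `beta`, target pucker class, and the pair placement
#'   parameter `x_disp` (A).
#' @export
helix_form <- function(name = c("A", "B")) {
  name <- match.arg(name)
  f <- switch(name,
    A = list(name = "A", twist = 32.7, rise = 2.81, P = 18, numax = 38,
             chi = -158, chi_off_pur = -13.53, chi_off_pyr = -3.81,
             gamma = 54, beta = 178,
             target_pucker = "C3'-endo", x_disp = -3.062, pp_target = 5.9),
    B = list(name = "B", twist = 36.0, rise = 3.38, P = 148, numax = 38,
             chi = -102, chi_off_pur = -21.64, chi_off_pyr = -0.83,
             gamma = 54.64, beta = -179.85,
             target_pucker = "C2'-endo", x_disp = -4.24, pp_target = 7.0))
  class(f) <- "helix_form"
  f
}

## Glycosidic chi used by the generator for one residue code: the form's
## nominal chi plus a small pinned per-class offset that keeps the backbone
## O3'-P step continuous across purine/pyrimidine steps.
form_chi <- function(form, code) {
  off <- if (is_purine(code)) form$chi_off_pur else form$chi_off_pyr
  if (is.null(off)) off <- 0
  form$chi + off
}

## Planarize a base (+ C1') into z = 0 with the glycosidic N at the origin
## and the N -> chi-atom bond along +x.
planar_base <- function(code) {
  tpl <- residue_templates()[[code]]
  ic <- nt_internal(code)
  names_use <- c(tpl$base_atoms, "C1'")
  m <- tpl$xyz[names_use, , drop = FALSE]
  b <- tpl$xyz[tpl$base_atoms, , drop = FALSE]
  ctr <- colMeans(b)
  sv <- svd(sweep(b, 2, ctr))
  normal <- sv$v[, 3]
  R1 <- rot_between(normal, c(0, 0, 1))
  m <- sweep(m, 2, ctr) %*% t(R1)
  m <- sweep(m, 2, m[ic$n_g, ])
  v <- m[ic$chi_atom, ]
  th <- atan2(v[2], v[1]) * DEG
  m <- m %*% t(rot_z(-th))
  ## deterministic face: N -> chi-atom -> second-neighbor counterclockwise
  ## (flip about the glycosidic x-axis if needed; a proper rotation)
  w <- m[ic$chi2_atom, ]
  if (w[2] < 0) m <- m %*% t(rot_x(180))
  m
}

## In-plane rigid transform of a flipped complement base minimizing the
## squared deviation of the WC donor-acceptor distances from 2.9 A (plus a
## weak C1'-C1' = 10.4 A term that fixes the under-determined A-U case).
ideal_pair <- function(pair_type) {
  key <- paste0("pair_", pair_type)
  if (!is.null(.template_env[[key]])) return(.template_env[[key]])
  codes <- strsplit(pair_type, "-")[[1]]
  b1 <- planar_base(codes[1])
  b2 <- planar_base(codes[2])
  hb <- WC_HBONDS[[pair_type]]
  b2f <- b2 %*% t(rot_x(180))
  ## the two-bond A-U pair leaves a near-degenerate rotation; the standard
  ## C2(A)-O2(U) contact (~3.6 A) and the C1'-C1' distance pin it down
  extra <- if (pair_type == "A-U") list(c("C2", "O2", 3.6)) else list()
  obj <- function(par) {
    m2 <- sweep(b2f %*% t(rot_z(par[3])), 2, -c(par[1], par[2], 0))
    e <- 0
    for (p in hb) e <- e + (vnorm(b1[p[1], ] - m2[p[2], ]) - 2.90)^2
    for (p in extra) {
      e <- e + 0.3 * (vnorm(b1[p[1], ] - m2[p[2], ]) - as.numeric(p[3]))^2
    }
    e + 0.3 * (vnorm(b1["C1'", ] - m2["C1'", ]) - 10.4)^2
  }
  best <- NULL
  for (th0 in seq(0, 330, by = 30)) {
    for (tx0 in c(6, 8, 10)) {
      fit <- stats::optim(c(tx0, 0, th0), obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
      fit <- stats::optim(fit$par, obj, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  par <- best$par
  m2 <- sweep(b2f %*% t(rot_z(par[3])), 2, -c(par[1], par[2], 0))
  ## canonicalize: midpoint of the C1'-C1' segment on the x-axis, the
  ## in-plane perpendicular bisector (pseudo-dyad) along x
  c1 <- b1["C1'", ]; c2 <- m2["C1'", ]
  mid <- (c1 + c2) / 2
  e <- (c2 - c1); e[3] <- 0; e <- unit(e)
  dyad <- c(-e[2], e[1], 0)
  ## orient the dyad towards the base side (deterministic sign choice)
  bc <- colMeans(rbind(b1[rownames(b1) != "C1'", , drop = FALSE],
                       m2[rownames(m2) != "C1'", , drop = FALSE]))
  if (sum(dyad * (bc - mid)) < 0) dyad <- -dyad
  th <- atan2(dyad[2], dyad[1]) * DEG
  Rz <- rot_z(-th)
  b1c <- sweep(b1, 2, mid) %*% t(Rz)
  m2c <- sweep(m2, 2, mid) %*% t(Rz)
  out <- list(s1 = b1c, s2 = m2c, hbond_err = sqrt(best$value / length(hb)))
  .template_env[[key]] <- out
  out
}

## Strand-1 base placement (base atoms + C1') for each code, in the
## canonical pair frame: for b paired with comp(b), the partner placement is
## exactly rot_x(180) applied to the strand-1 placement of comp(b).
strand1_placement <- function(code) {
  key <- paste0("s1_", code)
  if (!is.null(.template_env[[key]])) return(.template_env[[key]])
  p <- switch(code,
    G = ideal_pair("G-C")$s1,
    C = ideal_pair("G-C")$s2 %*% t(rot_x(180)),
    A = ideal_pair("A-U")$s1,
    U = ideal_pair("A-U")$s2 %*% t(rot_x(180)))
  .template_env[[key]] <- p
  p
}

#' Reverse complement of an RNA sequence
#' @param seq character scalar over A/C/G/U.
#' @return character scalar.
#' @export
reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

check_sequence <- function(seq) {
  if (grepl("[^ACGU]", seq)) {
    stop("sequence error: non-ACGU letter in ", seq)
  }
  strsplit(seq, "")[[1]]
}

## Build the atoms of one placed residue: parametric local nucleotide fitted
## rigidly onto a target base placement (base atoms + C1'), transformed by
## (R_helix, t_helix).
place_residue <- function(code, target_base, Rh, th, form,
                          with_phosphate = TRUE, P = form$P,
                          chi = form_chi(form, code)) {
  loc <- build_nucleotide(code, P = P, numax = form$numax, chi = chi,
                          gamma = form$gamma, beta = form$beta,
                          with_phosphate = with_phosphate)
  anchor <- c(residue_templates()[[code]]$base_atoms, "C1'")
  fit <- kabsch_superpose(loc[anchor, , drop = FALSE],
                          target_base[anchor, , drop = FALSE])
  placed <- xform(loc, fit$rotation, fit$translation)
  xform(placed, Rh, th)
}

residue_df <- function(chain, resi, code, xyz) {
  data.frame(chain = chain, resi = resi, resn = code,
             name = rownames(xyz),
             elem = substr(rownames(xyz), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build an ideal regular duplex
#'
#' Two antiparallel chains: chain `A` carries `seq` 5' to 3', chain `B` its
#' reverse complement. Every Watson-Crick pair satisfies the donor-acceptor
#' detection cutoffs, every sugar is in the form's target pucker, and every
#' residue is D.
#'
#' @param seq strand-1 sequence (length >= 2, A/C/G/U).
#' @param form a [helix_form()] (or `"A"`/`"B"`).
#' @param chain_ids two chain identifiers.
#' @param five_prime_phosphate logical of length 2: does each strand start
#'   with a 5'-phosphate? Default free 5'-OH termini.
#' @return an `rna_structure`.
#' @export
build_duplex <- function(seq, form = helix_form("A"), chain_ids = c("A", "B"),
                         five_prime_phosphate = c(FALSE, FALSE)) {
  if (is.character(form)) form <- helix_form(form)
  geo <- duplex_geometry(seq, form, five_prime_phosphate)
  n <- length(geo$strand1)
  rows <- list()
  s1 <- check_sequence(seq); s2 <- check_sequence(reverse_complement(seq))
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- residue_df(chain_ids[1], i, s1[i], geo$strand1[[i]])
    rows[[length(rows) + 1L]] <- residue_df(chain_ids[2], i, s2[i], geo$strand2[[i]])
  }
  fpp <- c(five_prime_phosphate[1], five_prime_phosphate[2])
  names(fpp) <- chain_ids
  rna_structure(do.call(rbind, rows), five_prime_phosphate = fpp)
}

## Coordinates of both strands of an ideal duplex, as lists of per-residue
## coordinate matrices indexed 5'->3' along each strand. Strand-1 residue i
## pairs strand-2 residue n - i + 1.
duplex_geometry <- function(seq, form, five_prime_phosphate = c(FALSE, FALSE)) {
  s1 <- check_sequence(seq)
  n <- length(s1)
  if (n < 2) stop("sequence error: duplex needs length >= 2")
  s2 <- check_sequence(reverse_complement(seq))
  shift <- c(form$x_disp, 0, 0)
  strand1 <- vector("list", n); strand2 <- vector("list", n)
  for (i in seq_len(n)) {
    Rh <- rot_z((i - 1) * form$twist)
    th <- c(0, 0, (i - 1) * form$rise)
    base1 <- sweep(strand1_placement(s1[i]), 2, -shift)
    wp1 <- if (i == 1) five_prime_phosphate[1] else TRUE
    strand1[[i]] <- place_residue(s1[i], base1, Rh, th, form, with_phosphate = wp1)
    j <- n - i + 1
    base2 <- sweep(strand1_placement(s2[j]), 2, -shift) %*% t(rot_x(180))
    wp2 <- if (j == 1) five_prime_phosphate[2] else TRUE
    strand2[[j]] <- place_residue(s2[j], base2, Rh, th, form, with_phosphate = wp2)
  }
  list(strand1 = strand1, strand2 = strand2)
}
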
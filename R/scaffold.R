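## Hammerhead two-strand scaffold: the three helices are ideal A-form
## segments arranged in a three-way layout; unpaired core/loop residues are
## placed on smooth connecting arcs with a 2.5 A clash floor. The scaffold
## is a topologically valid analysis fixture (all mapped Watson-Crick pairs
## pass 3D detection, all residues D), NOT a physical fold prediction.

## Rigid transform placing a built helix along direction `u` (unit, xy
## plane), junction (z = 0) end offset `off` from the origin.
helix_transform <- function(theta_deg, off = 9) {
  u <- c(cos(theta_deg / DEG), sin(theta_deg / DEG), 0)
  R <- rot_between(c(0, 0, 1), u)
  list(R = R, t = off * u, u = u)
}

## Place `m` single residues along a quadratic Bezier arc between two anchor
## points, oriented with the backbone (P -> O3') along the path tangent.
arc_residues <- function(codes, p_start, p_end, bulge = 8, form = helix_form("A")) {
  m <- length(codes)
  mid <- (p_start + p_end) / 2
  nrm <- if (vnorm(mid) > 1e-6) unit(mid) else c(0, 0, 1)
  ctrl <- mid + bulge * nrm
  bez <- function(t) {
    (1 - t)^2 * p_start + 2 * t * (1 - t) * ctrl + t^2 * p_end
  }
  out <- vector("list", m)
  for (k in seq_len(m)) {
    t <- k / (m + 1)
    pos <- bez(t)
    tng <- unit(2 * (1 - t) * (ctrl - p_start) + 2 * t * (p_end - ctrl))
    loc <- build_nucleotide(codes[k], P = form$P, numax = form$numax,
                            chi = form$chi, gamma = form$gamma,
                            beta = form$beta, with_phosphate = TRUE)
    v <- unit(loc["O3'", ] - loc["P", ])
    R <- rot_between(v, tng)
    ctr <- (loc["P", ] + loc["O3'", ]) / 2
    out[[k]] <- xform(sweep(loc, 2, ctr), R, pos)
  }
  out
}

#' Build a hammerhead two-strand scaffold
#'
#' All-D scaffold for the given ribozyme/substrate pair: helices 1, 2, 3
#' are ideal A-form segments placed in a three-way-junction layout, the
#' catalytic-core, tetraloop and dangling residues lie on smooth connecting
#' arcs (clash floor 2.5 Angstrom). Every mapped Watson-Crick pair passes
#' 3D detection by construction. The scaffold is a documented analysis test
#' fixture, not a folding prediction.
#'
#' @param ribozyme_seq,substrate_seq the two sequences, 5' to 3'.
#' @param pairing a [hammerhead_pairing()] map; derived from the sequences
#'   when omitted.
#' @param form helix form for the stems (A-form default).
#' @return an `rna_structure` with the ribozyme and substrate chains named
#'   as in `pairing$chains`; the pairing map is attached as attribute
#'   `pairing`.
#' @export
build_hammerhead_scaffold <- function(ribozyme_seq, substrate_seq,
                                      pairing = NULL,
                                      form = helix_form("A")) {
  if (is.character(form)) form <- helix_form(form)
  if (is.null(pairing)) {
    pairing <- hammerhead_pairing(ribozyme_seq, substrate_seq)
  }
  rz <- check_sequence(ribozyme_seq)
  sub <- check_sequence(substrate_seq)
  nr <- length(rz); ns <- length(sub)
  chR <- pairing$chains[1]; chS <- pairing$chains[2]
  pr <- pairing$pairs
  h1 <- pr[pr$helix == "H1", ]; h2 <- pr[pr$helix == "H2", ]
  h3 <- pr[pr$helix == "H3", ]
  L1 <- nrow(h1); L2 <- nrow(h2); L3 <- nrow(h3)
  s0 <- min(h2$resi1); e0 <- max(h2$resi2)
  j0 <- min(h3$resi2)
  res <- list() # key "chain|resi" -> xyz matrix
  put <- function(chain, resi, xyz) res[[paste(chain, resi)]] <<- xyz
  ## --- helix 1: substrate 3'-flank (strand 1) x ribozyme 5'-arm ---
  T1 <- helix_transform(0)
  g <- duplex_geometry(paste(sub[(ns - L1 + 1):ns], collapse = ""), form,
                       five_prime_phosphate = c(TRUE, FALSE))
  for (i in seq_len(L1)) {
    put(chS, ns - L1 + i, xform(g$strand1[[i]], T1$R, T1$t))
    put(chR, i, xform(g$strand2[[i]], T1$R, T1$t))
  }
  ## --- helix 3: ribozyme 3'-arm (strand 1) x substrate 5'-flank ---
  T3 <- helix_transform(135)
  g <- duplex_geometry(paste(rz[(nr - L3 + 1):nr], collapse = ""), form,
                       five_prime_phosphate = c(TRUE, TRUE))
  for (i in seq_len(L3)) {
    put(chR, nr - L3 + i, xform(g$strand1[[i]], T3$R, T3$t))
    put(chS, j0 + i - 1, xform(g$strand2[[i]], T3$R, T3$t))
  }
  ## --- helix 2: intramolecular stem, loop end distal ---
  T2 <- helix_transform(240)
  g <- duplex_geometry(paste(rz[s0:(s0 + L2 - 1)], collapse = ""), form,
                       five_prime_phosphate = c(TRUE, TRUE))
  for (i in seq_len(L2)) {
    put(chR, s0 + i - 1, xform(g$strand1[[i]], T2$R, T2$t))
    put(chR, e0 - L2 + i, xform(g$strand2[[i]], T2$R, T2$t))
  }
  ## --- connecting arcs ---
  anchor <- function(chain, resi, name) {
    m <- res[[paste(chain, resi)]]
    m[name, ]
  }
  seg <- function(chain, resis, codes, p_a, p_b, bulge = 8) {
    xs <- arc_residues(codes, p_a, p_b, bulge = bulge, form = form)
    for (k in seq_along(resis)) put(chain, resis[k], xs[[k]])
  }
  ## ribozyme core: after helix-1 arm up to the stem
  if (s0 - L1 > 1) {
    seg(chR, (L1 + 1):(s0 - 1), rz[(L1 + 1):(s0 - 1)],
        anchor(chR, L1, "O3'"), anchor(chR, s0, "P"), bulge = 9)
  }
  ## tetraloop closing the stem
  loop <- pairing$loop
  seg(chR, loop, rz[loop],
      anchor(chR, s0 + L2 - 1, "O3'"), anchor(chR, e0 - L2 + 1, "P"),
      bulge = 7)
  ## ribozyme core: stem exit to helix-3 arm
  if (nr - L3 > e0) {
    seg(chR, (e0 + 1):(nr - L3), rz[(e0 + 1):(nr - L3)],
        anchor(chR, e0, "O3'"), anchor(chR, nr - L3 + 1, "P"), bulge = 9)
  }
  ## substrate: cleavage-site region between the helix-3 and helix-1 arms
  gap <- setdiff(seq_len(ns), c((ns - L1 + 1):ns, j0:(j0 + L3 - 1)))
  core_gap <- gap[gap > j0]
  if (length(core_gap)) {
    seg(chS, core_gap, sub[core_gap],
        anchor(chS, max(j0 + L3 - 1, 1), "O3'"),
        anchor(chS, ns - L1 + 1, "P"), bulge = 6)
  }
  ## substrate 5' dangle before helix 3
  dangle <- gap[gap < j0]
  if (length(dangle)) {
    p0 <- anchor(chS, j0, "P")
    dir <- unit(T3$u + c(0, 0, 0.4))
    for (k in seq_along(rev(dangle))) {
      resi <- rev(dangle)[k]
      loc <- build_nucleotide(sub[resi], P = form$P, numax = form$numax,
                              chi = form$chi, gamma = form$gamma,
                              beta = form$beta,
                              with_phosphate = resi > 1)
      ctr <- colMeans(loc[intersect(c("C1'", "O3'"), rownames(loc)), , drop = FALSE])
      put(chS, resi, xform(sweep(loc, 2, ctr), rot_between(c(0, 0, 1), dir),
                           p0 + 6.5 * k * dir))
    }
  }
  ## --- clash relief for arc-placed residues (floor 2.5 A) ---
  arc_keys <- setdiff(names(res), c(
    paste(chR, c(seq_len(L1), s0:(s0 + L2 - 1), (e0 - L2 + 1):e0,
                 (nr - L3 + 1):nr)),
    paste(chS, c((ns - L1 + 1):ns, j0:(j0 + L3 - 1)))))
  neighbours <- function(key) {
    p <- strsplit(key, " ")[[1]]
    i <- as.integer(p[2])
    paste(p[1], c(i - 1, i, i + 1))
  }
  for (pass in 1:20) {
    moved <- FALSE
    for (key in arc_keys) {
      m <- res[[key]]
      ## bonded/adjacent residues are excluded from the clash floor
      others <- do.call(rbind, res[setdiff(names(res), neighbours(key))])
      dmin <- min(sqrt(pmax(0, outer(rowSums(m^2), rowSums(others^2), "+") -
                              2 * m %*% t(others))))
      if (is.na(dmin) || dmin >= 2.5) next
      ctr <- colMeans(m)
      dir <- if (vnorm(ctr) > 1e-6) unit(ctr) else c(0, 0, 1)
      res[[key]] <- sweep(m, 2, -1.0 * dir)
      moved <- TRUE
    }
    if (!moved) break
  }
  ## --- assemble ---
  rows <- list()
  for (resi in seq_len(nr)) {
    rows[[length(rows) + 1L]] <- residue_df(chR, resi, rz[resi],
                                            res[[paste(chR, resi)]])
  }
  for (resi in seq_len(ns)) {
    rows[[length(rows) + 1L]] <- residue_df(chS, resi, sub[resi],
                                            res[[paste(chS, resi)]])
  }
  fpp <- c(FALSE, FALSE)
  names(fpp) <- c(chR, chS)
  out <- rna_structure(do.call(rbind, rows), five_prime_phosphate = fpp)
  attr(out, "pairing") <- pairing
  out
}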
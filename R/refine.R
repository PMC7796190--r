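## Restrained first-order refinement: harmonic bonds (template ideals plus
## the inter-residue O3'-P linkage), harmonic angles, Watson-Crick H-bond
## harmonics (target 2.9 A), base-pair planarity harmonics, and optional
## harmonic position anchors on base heavy atoms of paired residues.
## Minimized by gradient descent with backtracking line search: the energy
## trace is monotonically non-increasing by construction and the whole
## procedure is deterministic.

O3P_BOND <- 1.607
INTER_ANGLES <- data.frame(
  a1 = c("C3'", "O3'", "O3'", "O3'"),
  a2 = c("O3'", "P", "P", "P"),
  a3 = c("P", "O5'", "OP1", "OP2"),
  th0 = c(119.7, 104.0, 108.1, 108.3))

#' Refinement settings
#'
#' @param steps maximal number of accepted gradient steps.
#' @param step_size initial step size, Angstrom per unit gradient.
#' @param k_bond,k_angle bond (kcal/mol A^-2) and angle (kcal/mol rad^-2)
#'   force constants.
#' @param k_hbond Watson-Crick H-bond constant (kcal/mol A^-2), target
#'   `hbond_target` (2.9 A).
#' @param k_planarity base-pair coplanarity constant (kcal/mol rad^-2).
#' @param k_anchor harmonic position restraint on base heavy atoms of
#'   paired residues (kcal/mol A^-2); 0 disables, 0.5 is the conventional
#'   gentle anchoring used during heterochiral conversion.
#' @param k_chirality harmonic restraint (kcal/mol A^-6) on the signed
#'   volume of each sugar chiral center toward its template magnitude with
#'   the residue's current handedness -- the analogue of the
#'   chirality-enforcing impropers of molecular-mechanics force fields.
#' @param max_move per-step cap on the largest atomic displacement,
#'   Angstrom (trust region).
#' @param hbond_target H-bond donor-acceptor target distance, Angstrom.
#' @param tol convergence tolerance on the energy decrease.
#' @return list of class `refinement_settings`.
#' @export
refinement_settings <- function(steps = 1000, step_size = 2e-4,
                                k_bond = 300, k_angle = 50, k_hbond = 10,
                                k_planarity = 5, k_anchor = 0,
                                k_chirality = 20, max_move = 0.05,
                                hbond_target = 2.9, tol = 1e-8) {
  stopifnot(steps >= 0, k_bond >= 0, k_angle >= 0, k_hbond >= 0,
            k_planarity >= 0, k_anchor >= 0, k_chirality >= 0, max_move > 0)
  structure(list(steps = steps, step_size = step_size, k_bond = k_bond,
                 k_angle = k_angle, k_hbond = k_hbond,
                 k_planarity = k_planarity, k_anchor = k_anchor,
                 k_chirality = k_chirality, max_move = max_move,
                 hbond_target = hbond_target, tol = tol),
            class = "refinement_settings")
}

## Build index-based restraint lists for a structure (+ pairing map).
restraint_terms <- function(x, pairing, settings) {
  a <- x$atoms
  akey <- paste(a$chain, a$resi, a$name)
  find <- function(chain, resi, name) match(paste(chain, resi, name), akey)
  rt <- residue_table(x)
  bonds_i <- integer(0); bonds_j <- integer(0); bonds_d0 <- numeric(0)
  ang_i <- integer(0); ang_j <- integer(0); ang_k <- integer(0); ang_t0 <- numeric(0)
  for (r in seq_len(nrow(rt))) {
    ch <- rt$chain[r]; ri <- rt$resi[r]
    ideals <- template_ideals(rt$resn[r])
    i1 <- find(ch, ri, ideals$bonds$a1)
    i2 <- find(ch, ri, ideals$bonds$a2)
    ok <- !is.na(i1) & !is.na(i2)
    bonds_i <- c(bonds_i, i1[ok]); bonds_j <- c(bonds_j, i2[ok])
    bonds_d0 <- c(bonds_d0, ideals$bonds$d0[ok])
    j1 <- find(ch, ri, ideals$angles$a1)
    j2 <- find(ch, ri, ideals$angles$ctr)
    j3 <- find(ch, ri, ideals$angles$a2)
    ok <- !is.na(j1) & !is.na(j2) & !is.na(j3)
    ang_i <- c(ang_i, j1[ok]); ang_j <- c(ang_j, j2[ok]); ang_k <- c(ang_k, j3[ok])
    ang_t0 <- c(ang_t0, ideals$angles$th0[ok])
    ## inter-residue linkage to the next residue of the same chain
    if (any(rt$chain == ch & rt$resi == ri + 1)) {
      p_next <- find(ch, ri + 1, "P")
      o3 <- find(ch, ri, "O3'")
      if (!is.na(p_next) && !is.na(o3)) {
        bonds_i <- c(bonds_i, o3); bonds_j <- c(bonds_j, p_next)
        bonds_d0 <- c(bonds_d0, O3P_BOND)
        ## first row is C3'(i)-O3'(i)-P(i+1); others O3'(i)-P(i+1)-X(i+1)
        for (q in seq_len(nrow(INTER_ANGLES))) {
          if (q == 1) {
            trip <- c(find(ch, ri, "C3'"), o3, p_next)
          } else {
            trip <- c(o3, p_next, find(ch, ri + 1, INTER_ANGLES$a3[q]))
          }
          if (!anyNA(trip)) {
            ang_i <- c(ang_i, trip[1]); ang_j <- c(ang_j, trip[2])
            ang_k <- c(ang_k, trip[3]); ang_t0 <- c(ang_t0, INTER_ANGLES$th0[q])
          }
        }
      }
    }
  }
  ## Watson-Crick restraints from the pairing map
  hb_i <- integer(0); hb_j <- integer(0)
  plan <- list()
  anchor_idx <- integer(0)
  if (!is.null(pairing)) {
    pr <- pairing$pairs
    for (k in seq_len(nrow(pr))) {
      type <- pr$type[k]
      if (!type %in% names(WC_HBONDS)) next
      pur_first <- is_purine(pr$resn1[k])
      c_pur <- if (pur_first) pr$chain1[k] else pr$chain2[k]
      r_pur <- if (pur_first) pr$resi1[k] else pr$resi2[k]
      c_pyr <- if (pur_first) pr$chain2[k] else pr$chain1[k]
      r_pyr <- if (pur_first) pr$resi2[k] else pr$resi1[k]
      for (p in WC_HBONDS[[type]]) {
        i <- find(c_pur, r_pur, p[1]); j <- find(c_pyr, r_pyr, p[2])
        if (!is.na(i) && !is.na(j)) { hb_i <- c(hb_i, i); hb_j <- c(hb_j, j) }
      }
      tri <- function(chain, resi, code) {
        n_g <- glyc_n(code)
        c(find(chain, resi, n_g),
          find(chain, resi, if (is_purine(code)) "C4" else "C2"),
          find(chain, resi, if (is_purine(code)) "C8" else "C6"))
      }
      t1 <- tri(pr$chain1[k], pr$resi1[k], pr$resn1[k])
      t2 <- tri(pr$chain2[k], pr$resi2[k], pr$resn2[k])
      if (!anyNA(t1) && !anyNA(t2)) plan[[length(plan) + 1L]] <- c(t1, t2)
      ## anchors: base heavy atoms of every Watson-Crick-paired residue
      for (side in 1:2) {
        ch <- pr[[paste0("chain", side)]][k]
        ri <- pr[[paste0("resi", side)]][k]
        code <- pr[[paste0("resn", side)]][k]
        anchor_idx <- c(anchor_idx, find(ch, ri, BASE_ATOMS[[code]]))
      }
    }
  }
  anchor_idx <- unique(anchor_idx[!is.na(anchor_idx)])
  ## chiral-center quadruples with target signed volumes: template
  ## magnitude, handedness taken from the current geometry
  ch_c <- integer(0); ch_1 <- integer(0); ch_2 <- integer(0); ch_3 <- integer(0)
  ch_v0 <- numeric(0)
  xyz0 <- coords(x)
  for (r in seq_len(nrow(rt))) {
    tpl <- residue_templates()[[rt$resn[r]]]
    centers <- tpl$chiral_centers
    for (ctr in names(centers)) {
      s <- centers[[ctr]]
      idx <- find(rt$chain[r], rt$resi[r], c(ctr, s))
      if (anyNA(idx)) next
      vcur <- chiral_volume(xyz0[idx[1], ], xyz0[idx[2], ], xyz0[idx[3], ],
                            xyz0[idx[4], ])
      vt <- tpl$xyz
      vmag <- abs(chiral_volume(vt[ctr, ], vt[s[1], ], vt[s[2], ], vt[s[3], ]))
      ch_c <- c(ch_c, idx[1]); ch_1 <- c(ch_1, idx[2])
      ch_2 <- c(ch_2, idx[3]); ch_3 <- c(ch_3, idx[4])
      ch_v0 <- c(ch_v0, sign(vcur) * vmag)
    }
  }
  list(bonds = list(i = bonds_i, j = bonds_j, d0 = bonds_d0),
       angles = list(i = ang_i, j = ang_j, k = ang_k,
                     t0 = ang_t0 / DEG),
       hbonds = list(i = hb_i, j = hb_j),
       planarity = plan,
       chirals = list(c = ch_c, s1 = ch_1, s2 = ch_2, s3 = ch_3, v0 = ch_v0),
       anchors = anchor_idx)
}

## Energy and analytic gradient of all restraint terms (planarity gradient
## by local finite differences over its 6 defining atoms).
restraint_energy <- function(xyz, terms, settings, anchor_xyz = NULL,
                             grad = TRUE) {
  E <- 0
  G <- if (grad) matrix(0, nrow(xyz), 3) else NULL
  acc <- function(idx, contrib) {
    r <- rowsum(contrib, group = idx)
    ii <- as.integer(rownames(r))
    G[ii, ] <<- G[ii, , drop = FALSE] + r
  }
  ## bonds + hbonds share the pair-harmonic form
  pair_term <- function(i, j, d0, kk) {
    if (!length(i)) return(invisible())
    dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
    d <- sqrt(rowSums(dv * dv))
    if (any(d < 1e-8)) stop("refinement error: coincident atoms")
    E <<- E + sum(kk * (d - d0)^2)
    if (grad) {
      gmag <- 2 * kk * (d - d0) / d
      gv <- dv * gmag
      acc(i, gv); acc(j, -gv)
    }
  }
  pair_term(terms$bonds$i, terms$bonds$j, terms$bonds$d0, settings$k_bond)
  pair_term(terms$hbonds$i, terms$hbonds$j, settings$hbond_target,
            settings$k_hbond)
  ## angles
  ai <- terms$angles$i
  if (length(ai)) {
    aj <- terms$angles$j; ak <- terms$angles$k; t0 <- terms$angles$t0
    u <- xyz[ai, , drop = FALSE] - xyz[aj, , drop = FALSE]
    v <- xyz[ak, , drop = FALSE] - xyz[aj, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    E <- E + sum(settings$k_angle * (th - t0)^2)
    if (grad) {
      sth <- sqrt(1 - cth^2)
      pref <- 2 * settings$k_angle * (th - t0) / sth
      gi <- -pref / nu * (v / nv - u / nu * cth)
      gk <- -pref / nv * (u / nu - v / nv * cth)
      acc(ai, gi); acc(ak, gk); acc(aj, -(gi + gk))
    }
  }
  ## planarity: angle between 3-atom base normals, harmonic about 0
  if (settings$k_planarity > 0 && length(terms$planarity)) {
    plan_e <- function(p) {
      n1 <- vcross(p[2, ] - p[1, ], p[3, ] - p[1, ])
      n2 <- vcross(p[5, ] - p[4, ], p[6, ] - p[4, ])
      c12 <- abs(sum(n1 * n2)) / (vnorm(n1) * vnorm(n2))
      ang <- acos(min(1 - 1e-12, c12))
      settings$k_planarity * ang^2
    }
    for (tr in terms$planarity) {
      p <- xyz[tr, , drop = FALSE]
      E <- E + plan_e(p)
      if (grad) {
        h <- 1e-5
        for (q in seq_len(6)) {
          for (d in 1:3) {
            p2 <- p; p2[q, d] <- p2[q, d] + h
            p3 <- p; p3[q, d] <- p3[q, d] - h
            G[tr[q], d] <- G[tr[q], d] + (plan_e(p2) - plan_e(p3)) / (2 * h)
          }
        }
      }
    }
  }
  ## chiral-volume harmonics: V = u . (v x w), dV analytic
  if (settings$k_chirality > 0 && length(terms$chirals$c)) {
    tc <- terms$chirals
    u <- xyz[tc$s1, , drop = FALSE] - xyz[tc$c, , drop = FALSE]
    v <- xyz[tc$s2, , drop = FALSE] - xyz[tc$c, , drop = FALSE]
    w <- xyz[tc$s3, , drop = FALSE] - xyz[tc$c, , drop = FALSE]
    vw <- rowcross(v, w)
    V <- rowdot(u, vw)
    E <- E + sum(settings$k_chirality * (V - tc$v0)^2)
    if (grad) {
      pref <- 2 * settings$k_chirality * (V - tc$v0)
      g1 <- vw * pref
      g2 <- rowcross(w, u) * pref
      g3 <- rowcross(u, v) * pref
      acc(tc$s1, g1); acc(tc$s2, g2); acc(tc$s3, g3)
      acc(tc$c, -(g1 + g2 + g3))
    }
  }
  ## position anchors
  if (!is.null(anchor_xyz) && settings$k_anchor > 0 && length(terms$anchors)) {
    dv <- xyz[terms$anchors, , drop = FALSE] - anchor_xyz
    E <- E + settings$k_anchor * sum(dv * dv)
    if (grad) acc(terms$anchors, 2 * settings$k_anchor * dv)
  }
  if (!is.finite(E)) stop("refinement error: non-finite energy")
  list(E = E, G = G)
}

#' Restrained refinement of a complex
#'
#' Gradient descent with backtracking on the restraint energy: harmonic
#' bonds and angles toward template ideals, Watson-Crick H-bond harmonics
#' at 2.9 Angstrom and base-pair planarity harmonics for every mapped pair,
#' plus optional position anchors on paired-base heavy atoms. The energy
#' trace is monotone non-increasing; the procedure is deterministic.
#'
#' @param x an `rna_structure`.
#' @param pairing a `pairing_map` (or `NULL` for covalent-geometry-only
#'   refinement).
#' @param settings a [refinement_settings()].
#' @return list with `structure` (refined), `trace` (energy per accepted
#'   step, starting at the input energy), `converged`.
#' @export
restrained_refine <- function(x, pairing = attr(x, "pairing"),
                              settings = refinement_settings()) {
  stopifnot(inherits(x, "rna_structure"))
  terms <- restraint_terms(x, pairing, settings)
  xyz <- coords(x)
  anchor_xyz <- if (length(terms$anchors)) xyz[terms$anchors, , drop = FALSE]
  eg <- restraint_energy(xyz, terms, settings, anchor_xyz)
  trace <- eg$E
  step <- settings$step_size
  converged <- FALSE
  nstep <- 0L
  while (nstep < settings$steps) {
    gnorm <- sqrt(sum(eg$G^2))
    if (gnorm < 1e-10) { converged <- TRUE; break }
    accepted <- FALSE
    gmax <- max(abs(eg$G))
    if (step * gmax > settings$max_move) step <- settings$max_move / gmax
    for (try in 1:30) {
      cand <- xyz - step * eg$G
      ce <- restraint_energy(cand, terms, settings, anchor_xyz, grad = FALSE)
      if (ce$E <= eg$E) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    delta <- eg$E - ce$E
    xyz <- cand
    eg <- restraint_energy(xyz, terms, settings, anchor_xyz)
    trace <- c(trace, eg$E)
    nstep <- nstep + 1L
    step <- step * 1.25
    if (delta < settings$tol * max(1, abs(eg$E))) { converged <- TRUE; break }
  }
  coords(x) <- xyz
  list(structure = x, trace = trace, converged = converged)
}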
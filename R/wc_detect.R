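## Geometric Watson-Crick pair detection: a pair is reported when every
## type-specific donor-acceptor distance is within the cutoff and the base
## planes are roughly coplanar (small angle between base normals).

base_normal <- function(x, chain, resi) {
  res <- residue_atoms(x, chain, resi)
  code <- res$resn[1]
  b <- residue_xyz(x, chain, resi, BASE_ATOMS[[code]])
  sv <- svd(sweep(b, 2, colMeans(b)))
  sv$v[, 3]
}

#' Detect Watson-Crick pairs from 3D geometry
#'
#' Scans all G/C and A/U residue combinations; a pair is reported when all
#' its type-specific donor-acceptor distances (G-C: O6-N4, N1-N3, N2-O2;
#' A-U: N6-O4, N1-N3) are at most `dmax` and the angle between the two base
#' normals is at most `planarity_max`. Pairs are labelled homochiral or
#' heterochiral from the residues' D/L labels.
#'
#' @param x an `rna_structure`.
#' @param dmax donor-acceptor distance cutoff, Angstrom.
#' @param planarity_max maximal inter-base-normal angle, degrees.
#' @return data frame with one row per detected pair: chain1, resi1, resn1,
#'   chain2, resi2, resn2, type, chirality_class, max_hbond (Angstrom),
#'   planarity (degrees). Empty data frame when nothing is detected.
#' @export
detect_wc_pairs_3d <- function(x, dmax = 3.5, planarity_max = 35) {
  rt <- residue_table(x)
  n <- nrow(rt)
  out <- list()
  if (n < 2) return(empty_pairs())
  ## precompute per-residue donor/acceptor coordinates, normals, chirality
  info <- vector("list", n)
  for (k in seq_len(n)) {
    code <- rt$resn[k]
    need <- unique(unlist(WC_HBONDS))
    have <- intersect(need, residue_atoms(x, rt$chain[k], rt$resi[k])$name)
    info[[k]] <- list(
      code = code,
      xyz = residue_xyz(x, rt$chain[k], rt$resi[k], have),
      normal = tryCatch(base_normal(x, rt$chain[k], rt$resi[k]),
                        error = function(e) NULL),
      chir = tryCatch(
        as.character(classify_residue_chirality(x, rt$chain[k], rt$resi[k])),
        error = function(e) "unknown"))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- info[[i]]$code; cj <- info[[j]]$code
      pt <- paste(sort(c(ci, cj), decreasing = TRUE), collapse = "-")
      if (pt == "U-A") pt <- "A-U"
      if (!pt %in% names(WC_HBONDS)) next
      ## order so the purine supplies the first atom of each H-bond pair
      pur_first <- is_purine(ci)
      a <- if (pur_first) info[[i]] else info[[j]]
      b <- if (pur_first) info[[j]] else info[[i]]
      hb <- WC_HBONDS[[pt]]
      dists <- vapply(hb, function(p) {
        if (!p[1] %in% rownames(a$xyz) || !p[2] %in% rownames(b$xyz)) {
          return(Inf)
        }
        vnorm(a$xyz[p[1], ] - b$xyz[p[2], ])
      }, numeric(1))
      if (any(dists > dmax)) next
      if (is.null(a$normal) || is.null(b$normal)) next
      cosang <- abs(sum(a$normal * b$normal))
      plan <- acos(max(-1, min(1, cosang))) * DEG
      if (plan > planarity_max) next
      chir_class <- if (info[[i]]$chir %in% c("D", "L") &&
                        info[[j]]$chir %in% c("D", "L")) {
        if (info[[i]]$chir == info[[j]]$chir) "homochiral" else "heterochiral"
      } else {
        "unknown"
      }
      out[[length(out) + 1L]] <- data.frame(
        chain1 = rt$chain[i], resi1 = rt$resi[i], resn1 = ci,
        chain2 = rt$chain[j], resi2 = rt$resi[j], resn2 = cj,
        type = pt, chirality_class = chir_class,
        max_hbond = max(dists), planarity = plan,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_pairs())
  do.call(rbind, out)
}

empty_pairs <- function() {
  data.frame(chain1 = character(0), resi1 = integer(0), resn1 = character(0),
             chain2 = character(0), resi2 = integer(0), resn2 = character(0),
             type = character(0), chirality_class = character(0),
             max_hbond = numeric(0), planarity = numeric(0),
             stringsAsFactors = FALSE)
}

## Match detected 3D pairs against a pairing map; returns the map's pairs
## with a `detected` logical column.
match_pairs <- function(detected, map) {
  key <- function(c1, r1, c2, r2) {
    k1 <- paste(c1, r1); k2 <- paste(c2, r2)
    paste(pmin(k1, k2), pmax(k1, k2), sep = "|")
  }
  dk <- key(detected$chain1, detected$resi1, detected$chain2, detected$resi2)
  mp <- map$pairs
  mp$detected <- key(mp$chain1, mp$resi1, mp$chain2, mp$resi2) %in% dk
  mp
}
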